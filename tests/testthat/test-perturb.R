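test_that("visuomotor rotation acts as an exact group action on trajectories", {
  ts <- generate_trial_set(10, seed = 1, toy_trial_config())
  expect_equal(apply_vr(ts, 0)$target, ts$target)
  expect_identical(apply_vr(ts, 45)$stimulus, ts$stimulus)
  # rotation of a known point
  one <- ts
  one$target[50, , 1] <- c(1, 0)
  expect_equal(apply_vr(one, 90)$target[50, , 1], c(0, 1), tolerance = 1e-12)
  # composition and inverse
  expect_equal(apply_vr(apply_vr(ts, 30), 30)$target,
               apply_vr(ts, 60)$target, tolerance = 1e-12)
  expect_equal(apply_vr(apply_vr(ts, 30), -30)$target, ts$target,
               tolerance = 1e-12)
})

test_that("reassociation swaps cues but not trajectories, and inverts exactly", {
  ts <- generate_trial_set(30, seed = 2, toy_trial_config())
  idp <- seq_len(8)
  expect_equal(apply_reassociation(ts, idp)$stimulus, ts$stimulus)
  perm <- c(5:8, 1:4)  # swap opposite targets
  re <- apply_reassociation(ts, perm)
  expect_identical(re$target, ts$target)
  expect_identical(re$go_step, ts$go_step)
  i <- which(ts$target_id == 1)[1]
  expect_equal(re$stimulus[1, 1:2, i], ts$targets$positions[5, ],
               ignore_attr = TRUE)
  expect_equal(re$cue_id, perm[ts$target_id])
  # applying the inverse permutation restores the original set
  inv <- order(perm)
  back <- apply_reassociation(re, inv)
  expect_equal(back$stimulus, ts$stimulus)
  expect_equal(back$cue_id, ts$cue_id)
  expect_error(apply_reassociation(ts, c(1, 1, 3:8)), "bijection")
})

test_that("random derangements have no fixed points and are reproducible", {
  for (s in 1:5) {
    d <- random_derangement(8, s)
    expect_true(all(d != 1:8))
    expect_setequal(d, 1:8)
  }
  expect_identical(random_derangement(8, 3), random_derangement(8, 3))
})

test_that("input remap exactly compensates a ring rotation without training", {
  p <- toy_params(N = 12, seed = 30)
  cfg <- toy_trial_config()
  es <- make_eval_set(cfg, go_s = 0.45)
  perm <- c(3:8, 1:2)  # cyclic shift = rotation of the cue ring
  expect_identical(input_remap(p, seq_len(8), es$targets), p)
  remapped <- input_remap(p, perm, es$targets)
  # only the cue channels of the input matrices may differ
  for (nm in c("W_up", "W_pmd", "W_m1", "W_up_pmd", "W_pmd_m1", "W_out"))
    expect_identical(remapped[[nm]], p[[nm]])
  expect_identical(remapped$W_in_up[, 3], p$W_in_up[, 3])
  # on the reassociated task the remapped network reproduces, for each reach
  # direction, the baseline network's trajectory for that direction
  re <- apply_reassociation(es, perm)
  for (i in c(1, 4, 7)) {
    base_out <- simulate_network(p, es$stimulus[, , i], rates = FALSE)$output
    remap_out <- simulate_network(remapped, re$stimulus[, , i],
                                  rates = FALSE)$output
    expect_equal(remap_out, base_out, tolerance = 1e-12)
  }
  # an arbitrary derangement of 8 ring positions is not a linear map
  expect_error(input_remap(p, c(2, 1, 4, 3, 6, 5, 8, 7), es$targets),
               "not representable")
})

test_that("synaptic fluctuation scales with the learned change as sqrt(1+f^2)", {
  p <- init_params(100, seed = 40)
  ts <- generate_trial_set(12, seed = 41, toy_trial_config())
  res <- train_network(p, ts, plasticity_mask("H_local"),
                       training_config(n_updates = 10, batch_size = 8,
                                       seed = 42))
  expect_identical(add_synaptic_fluctuation(res, 0), res$params_after)
  noisy <- add_synaptic_fluctuation(res, 10, seed = 43)
  for (nm in c("W_pmd", "W_m1", "W_pmd_m1")) {
    d_learned <- res$params_after[[nm]] - res$params_before[[nm]]
    d_total <- noisy[[nm]] - res$params_before[[nm]]
    ratio <- sd(as.numeric(d_total)) / sd(as.numeric(d_learned))
    expect_equal(ratio, sqrt(101), tolerance = 0.05)
  }
  # untouched groups
  expect_identical(noisy$W_up, res$params_after$W_up)
  expect_identical(add_synaptic_fluctuation(res, 10, seed = 43), noisy)
  # degenerate: no learned change
  res0 <- train_network(p, ts, plasticity_mask("H_local"),
                        training_config(n_updates = 0))
  res0$params_after <- res0$params_before
  expect_error(add_synaptic_fluctuation(res0, 10), "degenerate")
})
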