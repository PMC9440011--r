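test_that("targets are uniformly spaced on the circle and centred", {
  tg <- generate_targets(8, 1, 0)
  expect_equal(tg$positions[1, ], c(1, 0))
  expect_equal(diff(tg$angles), rep(pi / 4, 7))
  expect_equal(colSums(tg$positions), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(tg$positions^2)), rep(1, 8))

  tg4 <- generate_targets(4, 2, pi / 4)
  s2 <- sqrt(2)
  expect_equal(tg4$positions,
               cbind(c(s2, -s2, -s2, s2), c(s2, s2, -s2, -s2)),
               tolerance = 1e-12)

  expect_error(generate_targets(0), "n_targets")
  expect_error(generate_targets(8, -1), "radius")
})

test_that("minimum-jerk profile has exact endpoints and 1.875 d/D peak speed", {
  start <- c(0, 0); end <- c(3, 4); D <- 0.7; dt <- 0.001
  mj <- minimum_jerk_profile(start, end, D, dt)
  expect_equal(mj[1, ], start)
  expect_equal(mj[nrow(mj), ], end)
  speed <- sqrt(rowSums((diff(mj) / dt)^2))
  d <- sqrt(sum((end - start)^2))
  expect_equal(max(speed), 1.875 * d / D, tolerance = 1e-4)
  expect_equal(which.max(speed) / (nrow(mj) - 1), 0.5, tolerance = 2e-3)

  const <- minimum_jerk_profile(c(1, 2), c(1, 2), 0.5, 0.01)
  expect_true(all(const[, 1] == 1 & const[, 2] == 2))

  expect_error(minimum_jerk_profile(start, end, 0, dt), "duration")
  expect_error(minimum_jerk_profile(start, end, 0.01, 0.01), ">= 2")
})

test_that("build_trial lays out go channel and trajectory as specified", {
  cfg <- trial_config(T_steps = 400)
  tr <- build_trial(1, go_step = 100, cfg)
  expect_equal(tr$stimulus[, 3], as.numeric(seq_len(400) <= 100))
  # reaction 15 steps, movement 70 steps
  expect_true(all(tr$target[1:115, ] == 0))
  expect_true(tr$target[116, 1] != 0)
  pos <- generate_targets(8)$positions[1, ]
  expect_equal(tr$target[185, ], pos, tolerance = 1e-12)
  expect_true(all(tr$target[185:400, 1] == tr$target[185, 1]))
  # stimulus carries the target coordinates the whole trial
  expect_true(all(tr$stimulus[, 1] == pos[1] & tr$stimulus[, 2] == pos[2]))
  expect_error(build_trial(1, go_step = 390, cfg), "exceeds")
})

test_that("generate_trial_set is reproducible with balanced targets and split", {
  cfg <- trial_config()
  ts <- generate_trial_set(800, seed = 7, cfg)
  expect_equal(ts$n_trials, 800)
  expect_equal(sum(ts$split == "train"), 720)
  # per-target counts within 3 s.d. of 100 under Binomial(800, 1/8)
  counts <- tabulate(ts$target_id, 8)
  bound <- 3 * sqrt(800 * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - 100) <= bound))
  ts2 <- generate_trial_set(800, seed = 7, cfg)
  expect_identical(ts, ts2)
  expect_error(generate_trial_set(4, 1, cfg), "at least")
})

test_that("go-channel step structure holds across a large generated sample", {
  ts <- generate_trial_set(1000, seed = 3, trial_config())
  for (i in seq_len(ts$n_trials)) {
    g <- ts$stimulus[, 3, i]
    k <- ts$go_step[i]
    if (any(g[seq_len(k)] != 1) || any(g[(k + 1):length(g)] != 0)) {
      fail(sprintf("trial %d violates the go-channel step structure", i))
    }
  }
  succeed()
})

test_that("delays are consistent with Uniform(0.5, 1.5) s", {
  cfg <- trial_config()
  set.seed(99)
  delays <- replicate(4, {
    ts <- generate_trial_set(2500, seed = sample.int(1e6, 1), cfg)
    ts$go_step * cfg$dt
  })
  # go steps are rounded to the 10 ms grid; de-round before testing
  ks <- suppressWarnings(
    stats::ks.test(as.numeric(delays) +
                     runif(length(delays), -0.005, 0.005), "punif", 0.5, 1.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("rotating the target layout by the phase step permutes target ids", {
  cfg0 <- trial_config(phase = 0)
  cfg1 <- trial_config(phase = pi / 4)
  t0 <- generate_targets(cfg0$n_targets, cfg0$radius, cfg0$phase)
  t1 <- generate_targets(cfg1$n_targets, cfg1$radius, cfg1$phase)
  # position k of the rotated layout equals position k+1 of the original
  perm <- c(2:8, 1)
  expect_equal(t1$positions, t0$positions[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("trial sets round-trip through the container format", {
  ts <- generate_trial_set(20, seed = 5, toy_trial_config())
  path <- tempfile(fileext = ".rds")
  write_trial_set(ts, path)
  expect_identical(read_trial_set(path), ts)
  csv <- tempfile(fileext = ".csv")
  export_trial_csv(ts, 3, csv)
  df <- read.csv(csv)
  expect_equal(df$go_channel, ts$stimulus[, 3, 3])
  expect_equal(df$target_x, ts$target[, 1, 3])
})
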