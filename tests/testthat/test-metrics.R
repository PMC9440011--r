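make_bundle <- function(stacked, groups = 1, K = nrow(stacked)) {
  structure(list(psth = list(stacked), stacked = stacked,
                 sigma = apply(stacked, 2, sd), K = K, window_s = 0.6,
                 groups = groups),
            class = "psth_bundle")
}

test_that("PSTH averaging, sigma and bin count behave as defined", {
  T_steps <- 260
  N <- 4
  set.seed(1)
  base <- matrix(rnorm(T_steps * N), T_steps, N)
  rates <- list(base, base, base)  # identical trials
  b <- compute_psth(rates, go_steps = c(130, 130, 130), groups = c(1, 1, 1))
  expect_equal(b$K, 121)
  expect_equal(b$psth[[1]], base[70:190, ])
  # constant-rate neuron has sigma exactly 0
  rates2 <- lapply(1:2, function(i) {
    m <- matrix(rnorm(T_steps * N), T_steps, N)
    m[, 2] <- 0.7
    m
  })
  b2 <- compute_psth(rates2, c(130, 130), c(1, 2))
  expect_equal(b2$sigma[2], 0)
  expect_error(compute_psth(rates, c(30, 130, 130), c(1, 1, 1)),
               "window")
})

test_that("activity change is 0 for identical epochs and 1 for a +sigma shift", {
  set.seed(2)
  stacked <- matrix(rnorm(121 * 5), 121, 5)
  b <- make_bundle(stacked)
  expect_equal(as.numeric(activity_change(b, b)), 0)
  shifted <- make_bundle(sweep(stacked, 2, b$sigma, "+"))
  expect_equal(as.numeric(activity_change(b, shifted)), 1, tolerance = 1e-12)
})

test_that("activity change matches a brute-force hand computation", {
  set.seed(3)
  base <- matrix(rnorm(12), 4, 3)
  adapt <- matrix(rnorm(12), 4, 3)
  bb <- make_bundle(base)
  ba <- make_bundle(adapt)
  # direct elementwise computation
  vals <- c()
  for (n in 1:3) for (t in 1:4)
    vals <- c(vals, abs(adapt[t, n] - base[t, n]) / sd(base[, n]))
  expect_equal(as.numeric(activity_change(bb, ba)), median(vals))
  # neurons under the sigma floor are excluded
  base2 <- base; base2[, 2] <- 5
  b2 <- make_bundle(base2)
  a2 <- make_bundle(adapt)
  expect_equal(attr(activity_change(b2, a2), "n_excluded"), 1)
})

test_that("covariance change is zero under scaling and row permutation", {
  set.seed(4)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Y <- X + matrix(rnorm(40 * 6, sd = 0.5), 40, 6)
  expect_equal(covariance_change(X, X), 0)
  expect_equal(covariance_change(X, 2 * X), 0, tolerance = 1e-12)
  expect_equal(covariance_change(X, X[sample(40), ]), 0, tolerance = 1e-12)
  cc <- covariance_change(X, Y)
  expect_true(cc > 0 && cc <= 2)
  expect_equal(covariance_change(X, Y, upper_only = TRUE),
               covariance_change(Y, X, upper_only = TRUE))
  expect_error(covariance_change(matrix(1, 10, 3), matrix(1, 10, 3)),
               "degenerate|standard deviation")
})

test_that("covariance change is invariant to consistent neuron relabeling", {
  set.seed(5)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Y <- matrix(rnorm(30 * 5), 30, 5)
  perm <- sample(5)
  expect_equal(covariance_change(X[, perm], Y[, perm]),
               covariance_change(X, Y), tolerance = 1e-12)
})

test_that("weight change matches the relative-magnitude definition", {
  set.seed(6)
  W <- matrix(rnorm(25), 5, 5)
  expect_equal(weight_change(W, W), 0)
  expect_equal(weight_change(W, 1.01 * W), 0.01, tolerance = 1e-12)
  Wb <- matrix(c(1, -2, 0.5, -0.25), 2, 2)
  Wa <- matrix(c(1.1, -1.8, 0.4, -0.35), 2, 2)
  by_hand <- median(c(0.1 / 1, 0.2 / 2, 0.1 / 0.5, 0.1 / 0.25))
  expect_equal(weight_change(Wb, Wa), by_hand)
  expect_error(weight_change(W, matrix(0, 2, 2)), "shapes")
})

test_that("participation ratio: rank-1 is 1, identity is n, invariances hold", {
  u <- rnorm(7); v <- rnorm(9)
  expect_equal(participation_ratio(outer(u, v)), 1, tolerance = 1e-10)
  expect_equal(participation_ratio(diag(12)), 12)
  set.seed(7)
  M <- matrix(rnorm(36), 6, 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(participation_ratio(Q %*% M), participation_ratio(M),
               tolerance = 1e-9)
  expect_equal(participation_ratio(3.7 * M), participation_ratio(M),
               tolerance = 1e-9)
  expect_error(participation_ratio(matrix(0, 3, 3)), "degenerate")
})

test_that("trajectory RMSE follows the windowed definition", {
  T_steps <- 120
  target <- matrix(rnorm(T_steps * 2), T_steps, 2)
  expect_equal(trajectory_rmse(target, target), 0)
  off <- target
  off[51:T_steps, 1] <- off[51:T_steps, 1] + 0.4
  expect_equal(trajectory_rmse(off, target), 0.4 / sqrt(2),
               tolerance = 1e-12)
  # offsets before the scoring window are ignored
  pre <- target
  pre[1:50, ] <- pre[1:50, ] + 100
  expect_equal(trajectory_rmse(pre, target), 0)
})

test_that("angular error measures the signed initial-direction mismatch", {
  cfg <- toy_trial_config()
  tr <- build_trial(2, go_step = 50, cfg)  # target at 45 degrees
  pos <- generate_targets(8)$positions[2, ]
  expect_equal(angular_error(tr$target, pos, 50), 0, tolerance = 1e-9)
  # rotating the produced trajectory rotates the error
  rot <- tr$target %*% t(matrix(c(cos(pi / 6), sin(pi / 6),
                                  -sin(pi / 6), cos(pi / 6)), 2, 2))
  expect_equal(angular_error(rot, pos, 50), 30, tolerance = 1e-6)
  # threshold 0: direction of the first post-go displacement
  prod0 <- matrix(0, 100, 2)
  prod0[61:100, ] <- matrix(rep(c(0.01, 0.01), each = 40), 40, 2)
  expect_equal(angular_error(prod0, c(1, 0), 60, threshold_fraction = 0),
               45, tolerance = 1e-9)
  expect_error(angular_error(matrix(0, 100, 2), c(1, 0), 50),
               "no movement")
})

test_that("identical deterministic epochs give zero activity and covariance change", {
  p <- toy_params(N = 10, seed = 50)
  es <- make_eval_set(toy_trial_config(), go_s = 0.45)
  e1 <- evaluate_network(p, es, window_s = 0.3)
  e2 <- evaluate_network(p, es, window_s = 0.3)
  ch <- epoch_changes(e1, e2)
  expect_equal(ch$activity_change, c(0, 0))
  expect_equal(ch$covariance_change, c(0, 0), tolerance = 1e-12)
})
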