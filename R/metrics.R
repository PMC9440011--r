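#' Go-aligned trial-averaged activity (PSTH)
#'
#' Averages single-trial rates per cue over a window centred on the go cue
#' (default +/- 600 ms; 121 bins at 10 ms, inclusive endpoints), and
#' computes the per-neuron standard deviation across all window bins and
#' cues. Because the model is deterministic and evaluation trials share a
#' canonical go time, one trial per cue is an exact average.
#'
#' @param rates list of T x N single-trial rate matrices.
#' @param go_steps go-cue step index per trial.
#' @param groups grouping key per trial (the presented cue id).
#' @param dt integration step, seconds.
#' @param window_s half-width of the go-aligned window, seconds.
#' @return object of class `psth_bundle`: `psth` (list of K x N matrices,
#'   one per group), `stacked` ((G*K) x N), `sigma` (length-N), `K`,
#'   `groups`.
#' @export
compute_psth <- function(rates, go_steps, groups, dt = 0.01,
                         window_s = 0.6) {
  stopifnot(length(rates) == length(go_steps),
            length(rates) == length(groups))
  w <- as.integer(round(window_s / dt))
  T_steps <- nrow(rates[[1]])
  if (any(go_steps - w < 1) || any(go_steps + w > T_steps))
    stop("go-aligned window does not fit inside the trial")
  keys <- sort(unique(groups))
  psth <- lapply(keys, function(k) {
    idx <- which(groups == k)
    if (length(idx) == 0) stop("no trials for group ", k)
    acc <- 0
    for (i in idx)
      acc <- acc + rates[[i]][(go_steps[i] - w):(go_steps[i] + w), ,
                              drop = FALSE]
    acc / length(idx)
  })
  names(psth) <- as.character(keys)
  stacked <- do.call(rbind, psth)
  structure(list(psth = psth, stacked = stacked,
                 sigma = apply(stacked, 2, sd), K = 2L * w + 1L,
                 window_s = window_s, groups = keys),
            class = "psth_bundle")
}

#' Relative change in trial-averaged activity
#'
#' Element-wise `|PSTH_adapt - PSTH_base| / sigma_base` over all neurons,
#' window bins and cues, summarized by the median. `sigma_base` is the
#' baseline epoch's per-neuron s.d. across time and cues; neurons whose
#' baseline s.d. falls below `sigma_floor` are excluded from the median
#' (their count is attached as attribute `n_excluded`).
#'
#' @param base,adapt `psth_bundle`s from the two epochs (sigma is taken from
#'   `base` only).
#' @param sigma_floor exclusion threshold for near-constant neurons.
#' @return scalar median relative activity change.
#' @export
activity_change <- function(base, adapt, sigma_floor = 1e-9) {
  if (!identical(dim(base$stacked), dim(adapt$stacked)))
    stop("epoch PSTH shapes differ")
  keep <- base$sigma >= sigma_floor
  if (!any(keep)) stop("all neurons below the sigma floor")
  d <- abs(adapt$stacked[, keep, drop = FALSE] -
           base$stacked[, keep, drop = FALSE])
  d <- sweep(d, 2, base$sigma[keep], "/")
  structure(median(d), n_excluded = sum(!keep))
}

#' Change in neural covariance between two epochs
#'
#' Computes the neuron-by-neuron covariance of the stacked (time x cue)
#' trial-averaged activity for each epoch and returns 1 minus the Pearson
#' correlation between corresponding entries of the two matrices (all `N^2`
#' entries by default; set `upper_only = TRUE` for the upper triangle).
#' 0 means identical statistical interactions; the value lies in [0, 2].
#'
#' @param base_rates,adapt_rates stacked trial-averaged activity, rows =
#'   time-and-cue observations, columns = neurons (e.g. the `stacked` field
#'   of a `psth_bundle`).
#' @param upper_only correlate only the upper triangle (diagonal included).
#' @return scalar covariance change.
#' @export
covariance_change <- function(base_rates, adapt_rates, upper_only = FALSE) {
  if (nrow(base_rates) < 2 || ncol(base_rates) < 2)
    stop("need at least 2 observations and 2 neurons")
  if (ncol(base_rates) != ncol(adapt_rates))
    stop("epochs have different numbers of neurons")
  cb <- cov(base_rates)
  ca <- cov(adapt_rates)
  if (upper_only) {
    sel <- upper.tri(cb, diag = TRUE)
    cb <- cb[sel]
    ca <- ca[sel]
  }
  if (sd(as.numeric(cb)) == 0 || sd(as.numeric(ca)) == 0)
    stop("degenerate input: constant covariance entries")
  1 - cor(as.numeric(cb), as.numeric(ca))
}

#' Median relative weight change
#'
#' Element-wise `|W_adapt - W_base| / |W_base|`, summarized by the median
#' over entries. Near-zero baseline weights are guarded by flooring the
#' denominator at machine epsilon times the Frobenius norm of `W_base`.
#'
#' @param W_base,W_adapt same-shape weight matrices.
#' @return scalar median relative change (0.01 means a 1% change).
#' @export
weight_change <- function(W_base, W_adapt) {
  if (!all(dim(as.matrix(W_base)) == dim(as.matrix(W_adapt))))
    stop("weight matrices have different shapes")
  denom <- pmax(abs(W_base), .Machine$double.eps * sqrt(sum(W_base^2)))
  median(abs(W_adapt - W_base) / denom)
}

#' Participation-ratio dimensionality
#'
#' `(sum k_i)^2 / sum k_i^2` over the singular values of a matrix: 1 for a
#' rank-1 matrix, n for an n x n identity, and about `0.72 n` for an n x n
#' i.i.d. Gaussian matrix. Invariant to orthogonal transforms and scalar
#' scaling.
#'
#' @param dW matrix (typically a weight-change matrix).
#' @return scalar effective dimensionality in `[1, min(dim(dW))]`.
#' @export
participation_ratio <- function(dW) {
  k <- svd(dW, nu = 0, nv = 0)$d
  if (all(k == 0)) stop("degenerate input: all-zero matrix")
  sum(k)^2 / sum(k^2)
}

#' Trajectory root-mean-squared error
#'
#' Root of the mean squared component error between produced and target 2-D
#' trajectories over steps `> start_step` (default 50, matching the loss
#' window).
#'
#' @param produced,target T x 2 trajectories.
#' @param start_step steps after this index are scored.
#' @return scalar RMSE.
#' @export
trajectory_rmse <- function(produced, target, start_step = 50) {
  if (!all(dim(produced) == dim(target)))
    stop("produced and target shapes differ")
  T_steps <- nrow(produced)
  if (start_step >= T_steps) stop("start_step must be below the trial length")
  sel <- (start_step + 1):T_steps
  sqrt(mean((produced[sel, ] - target[sel, ])^2))
}

#' Angular error of the initial reach direction
#'
#' Signed angle (degrees, counter-clockwise positive) between the reach
#' direction and the target direction, measured at the first step after the
#' go cue where the distance from the origin exceeds
#' `threshold_fraction * radius`.
#'
#' @param produced T x 2 produced trajectory.
#' @param target_position 2-D target location.
#' @param go_step go-cue step index.
#' @param threshold_fraction movement-onset threshold as a fraction of the
#'   target radius.
#' @param radius target radius; defaults to `|target_position|`.
#' @return signed angular error in degrees, in (-180, 180].
#' @export
angular_error <- function(produced, target_position, go_step,
                          threshold_fraction = 0.25, radius = NULL) {
  if (is.null(radius)) radius <- sqrt(sum(target_position^2))
  steps <- (go_step + 1):nrow(produced)
  d <- sqrt(produced[steps, 1]^2 + produced[steps, 2]^2)
  hit <- which(d > threshold_fraction * radius)
  if (length(hit) == 0)
    stop("no movement: trajectory never crosses the onset threshold")
  p <- produced[steps[hit[1]], ]
  ang <- atan2(p[2], p[1]) - atan2(target_position[2], target_position[1])
  ang <- ang - 2 * pi * round(ang / (2 * pi))
  ang * 180 / pi
}
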