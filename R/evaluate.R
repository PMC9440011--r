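#' Evaluate a network on a trial set
#'
#' Simulates every trial (double precision, deterministic), collects the
#' produced trajectories, and summarizes behaviour: pooled trajectory RMSE,
#' per-trial RMSE, reach endpoints, signed angular errors, and — when the
#' go-aligned window fits — per-module PSTH bundles grouped by presented
#' cue, for the activity and covariance metrics.
#'
#' @param params `network_params`.
#' @param trial_set a `trial_set` (typically [make_eval_set()] output or a
#'   test split).
#' @param window_s PSTH half-window, seconds; set `NULL` to skip PSTHs.
#' @param start_step RMSE scoring window start (see [trajectory_rmse()]).
#' @return object of class `network_evaluation`: `rmse`, `per_trial_rmse`,
#'   `endpoints` (n x 2), `angular_error` (degrees, NA where movement onset
#'   was never reached), `psth` (list `up`/`pmd`/`m1` of `psth_bundle`s or
#'   `NULL`), and the raw `records`.
#' @export
evaluate_network <- function(params, trial_set, window_s = 0.6,
                             start_step = 50) {
  records <- simulate_trial_set(params, trial_set)
  n <- trial_set$n_trials
  per_rmse <- numeric(n)
  ang <- rep(NA_real_, n)
  endpoints <- matrix(NA_real_, n, 2)
  T_steps <- trial_set$config$T_steps
  for (i in seq_len(n)) {
    out <- records[[i]]$output
    targ <- trial_set$target[, , i]
    per_rmse[i] <- trajectory_rmse(out, targ, start_step)
    endpoints[i, ] <- out[T_steps, ]
    ang[i] <- tryCatch(
      angular_error(out, targ[T_steps, ], trial_set$go_step[i],
                    radius = trial_set$config$radius),
      error = function(e) NA_real_)
  }
  psth <- NULL
  if (!is.null(window_s)) {
    w <- round(window_s / trial_set$config$dt)
    if (all(trial_set$go_step - w >= 1) &&
        all(trial_set$go_step + w <= T_steps)) {
      psth <- lapply(c(up = "r_up", pmd = "r_pmd", m1 = "r_m1"),
                     function(f) compute_psth(lapply(records, `[[`, f),
                                              trial_set$go_step,
                                              trial_set$cue_id,
                                              trial_set$config$dt, window_s))
    }
  }
  structure(list(rmse = sqrt(mean(per_rmse^2)), per_trial_rmse = per_rmse,
                 endpoints = endpoints, angular_error = ang, psth = psth,
                 records = records),
            class = "network_evaluation")
}

#' @export
print.network_evaluation <- function(x, ...) {
  cat(sprintf("<network_evaluation> %d trials, RMSE %.4g",
              length(x$per_trial_rmse), x$rmse))
  if (any(is.finite(x$angular_error)))
    cat(sprintf(", mean |angular error| %.1f deg",
                mean(abs(x$angular_error), na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Activity and covariance changes between two evaluations
#'
#' @param base,adapt `network_evaluation`s carrying PSTH bundles.
#' @param modules which modules to report.
#' @return data.frame with columns `module`, `activity_change`,
#'   `covariance_change`.
#' @export
epoch_changes <- function(base, adapt, modules = c("pmd", "m1")) {
  if (is.null(base$psth) || is.null(adapt$psth))
    stop("evaluations lack PSTH bundles (window did not fit?)")
  do.call(rbind, lapply(modules, function(m) data.frame(
    module = m,
    activity_change = as.numeric(
      activity_change(base$psth[[m]], adapt$psth[[m]])),
    covariance_change = covariance_change(base$psth[[m]]$stacked,
                                          adapt$psth[[m]]$stacked))))
}

#' Weight-change summary across parameter groups
#'
#' @param params_before,params_after `network_params` from before/after an
#'   adaptation.
#' @param groups parameter groups to summarize (default: the matrix groups).
#' @return data.frame with `group`, `weight_change` (median relative
#'   change) and `dimensionality` (participation ratio of the change
#'   matrix; NA for unchanged groups).
#' @export
weight_change_summary <- function(params_before, params_after,
                                  groups = setdiff(PARAM_GROUPS, "b_out")) {
  do.call(rbind, lapply(groups, function(nm) {
    dW <- params_after[[nm]] - params_before[[nm]]
    data.frame(
      group = nm,
      weight_change = weight_change(params_before[[nm]], params_after[[nm]]),
      dimensionality = if (all(dW == 0)) NA_real_
                       else participation_ratio(dW))
  }))
}
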