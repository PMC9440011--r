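#' Target layout for the centre-out reaching task
#'
#' Places `n_targets` reach targets uniformly on a circle of radius `radius`,
#' starting at angle `phase`. Eight targets on a unit circle is the standard
#' instructed-delay centre-out configuration.
#'
#' @param n_targets number of targets (>= 1).
#' @param radius circle radius in workspace units (> 0).
#' @param phase angle of the first target, radians.
#' @return An object of class `target_set`: list with `n_targets`, `radius`,
#'   `angles` (radians) and `positions` (`n_targets` x 2 matrix).
#' @examples
#' tg <- generate_targets(8)
#' colSums(tg$positions)  # centroid at the origin
#' @export
generate_targets <- function(n_targets = 8, radius = 1, phase = 0) {
  if (n_targets < 1) stop("n_targets must be >= 1")
  if (radius <= 0) stop("radius must be positive")
  angles <- phase + 2 * pi * (seq_len(n_targets) - 1) / n_targets
  positions <- cbind(radius * cos(angles), radius * sin(angles))
  structure(list(n_targets = as.integer(n_targets), radius = radius,
                 angles = angles, positions = positions),
            class = "target_set")
}

#' Minimum-jerk point-to-point trajectory
#'
#' Fifth-order minimum-jerk interpolation between two planar points:
#' `x(tau) = start + (end - start) * (10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = t/duration`. Used as the synthetic stand-in for recorded hand
#' trajectories; peak speed is `1.875 * d / duration` at the midpoint for a
#' straight reach of length `d`.
#'
#' @param start,end 2-D points.
#' @param duration movement time, seconds (> 0).
#' @param dt sampling step, seconds; `duration/dt` must be >= 2.
#' @return `(duration/dt + 1)` x 2 matrix of positions from `t = 0` to
#'   `t = duration` inclusive.
#' @export
minimum_jerk_profile <- function(start, end, duration, dt) {
  if (duration <= 0) stop("duration must be positive")
  if (dt <= 0) stop("dt must be positive")
  n <- round(duration / dt)
  if (n < 2) stop("duration/dt must be >= 2")
  tau <- seq(0, n) / n
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  cbind(start[1] + (end[1] - start[1]) * s,
        start[2] + (end[2] - start[2]) * s)
}

#' Trial-generator configuration
#'
#' Collects the task parameters shared by all trials of a set. Times are in
#' seconds; step counts derive from `dt`. The delay (target-to-go) range
#' defaults to the instructed-delay task's 0.5--1.5 s; the reaction and
#' movement times (150 ms / 700 ms) are monkey-like defaults for the
#' synthetic trajectories.
#'
#' @param n_targets,radius,phase passed to [generate_targets()].
#' @param T_steps trial length in steps.
#' @param dt integration step, seconds.
#' @param delay_range range of the variable delay between target onset and
#'   the go cue, seconds.
#' @param reaction_s,movement_s reaction and movement times, seconds.
#' @param train_frac fraction of trials labelled "train" in the split.
#' @return list of class `trial_config`.
#' @export
trial_config <- function(n_targets = 8, radius = 1, phase = 0, T_steps = 400,
                         dt = 0.01, delay_range = c(0.5, 1.5),
                         reaction_s = 0.15, movement_s = 0.7,
                         train_frac = 0.9) {
  cfg <- list(n_targets = as.integer(n_targets), radius = radius,
              phase = phase, T_steps = as.integer(T_steps), dt = dt,
              delay_range = delay_range,
              reaction_steps = as.integer(round(reaction_s / dt)),
              movement_steps = as.integer(round(movement_s / dt)),
              train_frac = train_frac)
  max_go <- round(max(delay_range) / dt)
  if (max_go + cfg$reaction_steps + cfg$movement_steps > cfg$T_steps)
    stop("longest delay + reaction + movement exceeds the trial length")
  if (train_frac < 0 || train_frac > 1) stop("train_frac must be in [0, 1]")
  class(cfg) <- "trial_config"
  cfg
}

#' Assemble one instructed-delay trial
#'
#' Builds the stimulus and target-trajectory time series for a single trial.
#' The stimulus carries the target x/y coordinates on dimensions 1--2 for the
#' whole trial and the go channel on dimension 3 (1 up to and including
#' `go_step`, 0 afterwards). The target trajectory rests at the origin until
#' `go_step + reaction_steps`, follows a minimum-jerk reach over
#' `movement_steps` steps, and holds at the target from step
#' `go_step + reaction_steps + movement_steps` to the end.
#'
#' @param target_id index into the configuration's target set.
#' @param go_step go-cue step index (delay = `go_step * dt`).
#' @param config a [trial_config()].
#' @param targets optional `target_set`; defaults to the one implied by
#'   `config`.
#' @param reaction_steps,movement_steps step counts; default from `config`.
#' @return list with `stimulus` (T x 3), `target` (T x 2), `go_step`,
#'   `target_id`, `cue_id`.
#' @export
build_trial <- function(target_id, go_step, config, targets = NULL,
                        reaction_steps = config$reaction_steps,
                        movement_steps = config$movement_steps) {
  if (is.null(targets))
    targets <- generate_targets(config$n_targets, config$radius, config$phase)
  T_steps <- config$T_steps
  if (go_step + reaction_steps + movement_steps > T_steps)
    stop("go_step + reaction + movement exceeds the trial length")
  pos <- targets$positions[target_id, ]
  stimulus <- matrix(0, T_steps, 3)
  stimulus[, 1] <- pos[1]
  stimulus[, 2] <- pos[2]
  stimulus[, 3] <- as.numeric(seq_len(T_steps) <= go_step)
  target <- matrix(0, T_steps, 2)
  onset <- go_step + reaction_steps
  mj <- minimum_jerk_profile(c(0, 0), pos, movement_steps * config$dt,
                             config$dt)
  target[onset + seq_len(movement_steps), ] <- mj[-1, ]
  if (onset + movement_steps < T_steps)
    target[(onset + movement_steps + 1):T_steps, ] <-
      matrix(pos, T_steps - onset - movement_steps, 2, byrow = TRUE)
  list(stimulus = stimulus, target = target, go_step = as.integer(go_step),
       target_id = as.integer(target_id), cue_id = as.integer(target_id))
}

new_trial_set <- function(stimulus, target, go_step, target_id, cue_id,
                          split, config, targets, seed = NA_integer_) {
  structure(list(stimulus = stimulus, target = target,
                 go_step = as.integer(go_step),
                 target_id = as.integer(target_id),
                 cue_id = as.integer(cue_id), split = split,
                 config = config, targets = targets,
                 seed = seed, n_trials = length(go_step)),
            class = "trial_set")
}

#' Generate a set of centre-out reaching trials
#'
#' Draws `n_trials` instructed-delay trials with targets sampled uniformly
#' and delays uniform over `config$delay_range`, then labels a random
#' `train_frac` of them "train" and the rest "test". Fully reproducible for
#' a fixed seed.
#'
#' @param n_trials number of trials (>= number of targets).
#' @param seed integer RNG seed.
#' @param config a [trial_config()].
#' @return A `trial_set`: arrays `stimulus` (T x 3 x n), `target`
#'   (T x 2 x n), vectors `go_step`, `target_id`, `cue_id`, `split`, plus the
#'   generating `config`, `targets`, and `seed`.
#' @export
generate_trial_set <- function(n_trials, seed, config = trial_config()) {
  if (n_trials < config$n_targets)
    stop("n_trials must be at least the number of targets")
  set.seed(seed)
  targets <- generate_targets(config$n_targets, config$radius, config$phase)
  target_id <- sample.int(config$n_targets, n_trials, replace = TRUE)
  delays <- runif(n_trials, config$delay_range[1], config$delay_range[2])
  go_step <- pmax(1L, as.integer(round(delays / config$dt)))
  n_train <- round(config$train_frac * n_trials)
  split <- rep("test", n_trials)
  split[sample.int(n_trials, n_train)] <- "train"
  stimulus <- array(0, c(config$T_steps, 3, n_trials))
  target <- array(0, c(config$T_steps, 2, n_trials))
  for (i in seq_len(n_trials)) {
    tr <- build_trial(target_id[i], go_step[i], config, targets)
    stimulus[, , i] <- tr$stimulus
    target[, , i] <- tr$target
  }
  new_trial_set(stimulus, target, go_step, target_id, target_id, split,
                config, targets, as.integer(seed))
}

#' Canonical-go evaluation set
#'
#' One trial per target with a shared go time, used for all metric
#' evaluations. Because the dynamics are deterministic and the go timing is
#' identical across repeats, a single trial per target is an exact
#' trial average.
#'
#' @param config a [trial_config()].
#' @param go_s canonical go time, seconds (default 1.0).
#' @return a `trial_set` with `n_targets` trials, all labelled "test".
#' @export
make_eval_set <- function(config = trial_config(), go_s = 1.0) {
  targets <- generate_targets(config$n_targets, config$radius, config$phase)
  go_step <- as.integer(round(go_s / config$dt))
  n <- config$n_targets
  stimulus <- array(0, c(config$T_steps, 3, n))
  target <- array(0, c(config$T_steps, 2, n))
  for (i in seq_len(n)) {
    tr <- build_trial(i, go_step, config, targets)
    stimulus[, , i] <- tr$stimulus
    target[, , i] <- tr$target
  }
  new_trial_set(stimulus, target, rep(go_step, n), seq_len(n), seq_len(n),
                rep("test", n), config, targets)
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %d trials, T = %d steps (dt = %g s), %d targets\n",
    x$n_trials, x$config$T_steps, x$config$dt, x$config$n_targets))
  cat(sprintf("  split: %d train / %d test\n",
              sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

subset_trial_set <- function(ts, idx) {
  new_trial_set(ts$stimulus[, , idx, drop = FALSE],
                ts$target[, , idx, drop = FALSE],
                ts$go_step[idx], ts$target_id[idx], ts$cue_id[idx],
                ts$split[idx], ts$config, ts$targets, ts$seed)
}
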