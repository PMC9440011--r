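rotation_matrix <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a visuomotor rotation to a trial set
#'
#' Rotates every target trajectory about the origin by `angle_deg`
#' (counter-clockwise positive) while leaving the stimuli untouched — the
#' network keeps seeing the original cues but must now produce rotated
#' reaches, mimicking rotated visual feedback.
#'
#' @param trial_set a `trial_set`.
#' @param angle_deg rotation angle in degrees.
#' @return the rotated `trial_set`.
#' @export
apply_vr <- function(trial_set, angle_deg) {
  R <- rotation_matrix(angle_deg)
  x <- trial_set$target[, 1, , drop = FALSE]
  y <- trial_set$target[, 2, , drop = FALSE]
  trial_set$target[, 1, ] <- R[1, 1] * x + R[1, 2] * y
  trial_set$target[, 2, ] <- R[2, 1] * x + R[2, 2] * y
  attr(trial_set, "vr_angle") <-
    (attr(trial_set, "vr_angle") %||% 0) + angle_deg
  trial_set
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_permutation <- function(perm, n) {
  if (length(perm) != n || !setequal(perm, seq_len(n)))
    stop("permutation must be a bijection on 1..", n)
  as.integer(perm)
}

#' Random derangement of target indices
#'
#' Uniformly samples a permutation with no fixed point (every cue reassigned
#' to a different direction), by rejection.
#'
#' @param n number of targets.
#' @param seed integer RNG seed.
#' @return integer permutation vector.
#' @export
random_derangement <- function(n, seed) {
  set.seed(seed)
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Reassociate cues with reach directions
#'
#' Implements the reassociation task: the trial whose required reach is to
#' target `k` now carries the visual cue of target `perm[k]` (stimulus
#' dimensions 1--2 replaced; go channel and target trajectory untouched).
#' `cue_id` records the presented cue, which is the grouping key for the
#' activity metrics. Repeated applications compose on the current cue
#' assignment, so a permutation followed by its inverse restores the
#' original set.
#'
#' @param trial_set a `trial_set`.
#' @param perm integer permutation over target ids.
#' @return the reassociated `trial_set`.
#' @export
apply_reassociation <- function(trial_set, perm) {
  perm <- check_permutation(perm, trial_set$config$n_targets)
  pos <- trial_set$targets$positions
  new_cue <- perm[trial_set$cue_id]
  for (i in seq_len(trial_set$n_trials)) {
    trial_set$stimulus[, 1, i] <- pos[new_cue[i], 1]
    trial_set$stimulus[, 2, i] <- pos[new_cue[i], 2]
  }
  trial_set$cue_id <- as.integer(new_cue)
  attr(trial_set, "reassociation") <- perm
  trial_set
}

#' Compensate a reassociation by remapping the input channels
#'
#' Training-free adaptation to a reassociation: the 2-D target-coordinate
#' input channels of both input matrices are composed with the linear map
#' that sends each reassigned cue position back to its required direction,
#' so that cue `perm[k]` evokes the input pattern originally driven by cue
#' `k`. For the 8-target ring this map exists exactly when the permutation
#' acts as a rotation/reflection of the ring; otherwise the position mapping
#' is not realizable by a linear map on two channels and an error is raised
#' (use [apply_reassociation()] with the inverse permutation on the
#' evaluation set for the exactly equivalent per-trial alternative). No
#' weight is trained; recurrent, feedforward and readout parameters are
#' returned bit-identical.
#'
#' @param params `network_params`.
#' @param perm the reassociation permutation (as given to
#'   [apply_reassociation()]).
#' @param targets the `target_set` defining cue positions.
#' @param tol residual tolerance for linear realizability.
#' @return remapped `network_params`.
#' @export
input_remap <- function(params, perm, targets, tol = 1e-8) {
  perm <- check_permutation(perm, targets$n_targets)
  P <- targets$positions          # cue k at row k
  Pp <- P[perm, , drop = FALSE]   # cue shown for direction k
  # want M such that M %*% Pp[k,] = P[k,] for all k
  Mt <- qr.solve(qr(Pp), P)       # least squares: Pp %*% Mt ~ P
  if (max(abs(Pp %*% Mt - P)) > tol)
    stop("reassociation is not representable by a linear map on the cue channels")
  M <- t(Mt)
  params$W_in_up[, 1:2] <- params$W_in_up[, 1:2] %*% M
  params$W_in_pmd[, 1:2] <- params$W_in_pmd[, 1:2] %*% M
  params
}

#' Inject synaptic fluctuations into the learned weight changes
#'
#' Adds i.i.d. zero-mean Gaussian noise to every parameter group that was
#' plastic during the adaptation, with per-group s.d. equal to `factor`
#' times the s.d. of that group's learned element-wise changes. No
#' connections are added or removed; groups outside the mask are untouched.
#'
#' @param result an `adaptation_result`.
#' @param factor noise scale relative to the learned-change s.d.
#'   (default 10).
#' @param seed integer RNG seed.
#' @return `network_params` with perturbed weights.
#' @export
add_synaptic_fluctuation <- function(result, factor = 10, seed = 1) {
  stopifnot(inherits(result, "adaptation_result"), factor >= 0)
  params <- result$params_after
  if (factor == 0) return(params)
  set.seed(seed)
  for (nm in unclass(result$mask)) {
    d <- as.numeric(result$params_after[[nm]]) -
      as.numeric(result$params_before[[nm]])
    s <- sd(d)
    if (!is.finite(s) || s == 0)
      stop("degenerate input: no learned change in group ", nm)
    noise <- rnorm(length(d), 0, factor * s)
    if (nm == "b_out") params[[nm]] <- params[[nm]] + noise
    else params[[nm]] <- params[[nm]] +
        matrix(noise, nrow(params[[nm]]), ncol(params[[nm]]))
  }
  params
}
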