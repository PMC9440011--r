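#' Plasticity masks for the competing learning hypotheses
#'
#' A plasticity mask names the parameter groups whose weights may change
#' during (re)training; gradients never flow into the others. The presets
#' encode the hypotheses about where adaptation-related plasticity occurs:
#' `H_input` restricts learning to the upstream module and its efferents
#' (`W_up`, `W_in_up`, `W_up_pmd`; the stimulus-to-PMd matrix is excluded —
#' set `include_w_in_pmd = TRUE` to add it), `H_local` to within PMd and M1
#' (`W_pmd`, `W_m1`, `W_pmd_m1`), and `de_novo` trains all nine groups
#' including the readout.
#'
#' @param hypothesis one of `"de_novo"`, `"H_input"`, `"H_local"`,
#'   `"custom"`.
#' @param groups for `"custom"`, a character vector of parameter-group names.
#' @param include_w_in_pmd also train `W_in_pmd` under `H_input`.
#' @return object of class `plasticity_mask` (character vector of trainable
#'   groups).
#' @export
plasticity_mask <- function(hypothesis = c("de_novo", "H_input", "H_local",
                                           "custom"),
                            groups = NULL, include_w_in_pmd = FALSE) {
  hypothesis <- match.arg(hypothesis)
  trainable <- switch(hypothesis,
    de_novo = PARAM_GROUPS,
    H_input = c("W_up", "W_in_up", "W_up_pmd",
                if (include_w_in_pmd) "W_in_pmd"),
    H_local = c("W_pmd", "W_m1", "W_pmd_m1"),
    custom = {
      if (is.null(groups)) stop("custom mask needs explicit groups")
      bad <- setdiff(groups, PARAM_GROUPS)
      if (length(bad)) stop("unknown parameter groups: ",
                            paste(bad, collapse = ", "))
      groups
    })
  if (length(trainable) == 0) stop("plasticity mask must be non-empty")
  structure(unique(trainable), class = "plasticity_mask",
            hypothesis = hypothesis)
}

#' @export
print.plasticity_mask <- function(x, ...) {
  cat(sprintf("<plasticity_mask> %s: {%s}\n", attr(x, "hypothesis"),
              paste(unclass(x), collapse = ", ")))
  invisible(x)
}

#' Train the network under a plasticity mask
#'
#' Runs `config$n_updates` Adam steps. Each update draws `batch_size` trials
#' with replacement from the training split, computes the regularized loss by
#' a full forward pass, backpropagates through time, zeroes the gradients of
#' the groups outside the mask, clips the global gradient norm of the
#' remaining groups at `grad_clip_norm`, and applies Adam. Groups outside the
#' mask are returned bit-identical.
#'
#' @param params starting `network_params`.
#' @param trial_set a `trial_set`; its "train" split is sampled from.
#' @param mask a [plasticity_mask()].
#' @param config a [training_config()].
#' @param task optional label stored with the result (e.g. the rotation
#'   angle).
#' @return object of class `adaptation_result`: `params_before`,
#'   `params_after`, `loss_history`, `error_history` (per-update batch
#'   trajectory RMSE), `mask`, `config`, `task`.
#' @export
train_network <- function(params, trial_set, mask, config = training_config(),
                          task = NULL) {
  validate_params(params)
  if (!inherits(mask, "plasticity_mask")) stop("mask must be a plasticity_mask")
  idx_train <- which(trial_set$split == "train")
  if (length(idx_train) == 0) idx_train <- seq_len(trial_set$n_trials)
  if (config$loss_start >= trial_set$config$T_steps)
    stop("loss_start must be below the trial length")
  if (config$n_updates == 0) {
    res <- list(params_before = params, params_after = params,
                loss_history = numeric(0), error_history = numeric(0),
                mask = mask, config = config, task = task)
    class(res) <- "adaptation_result"
    return(res)
  }
  set.seed(config$seed)
  batch_idx <- matrix(
    idx_train[sample.int(length(idx_train),
                         config$n_updates * config$batch_size,
                         replace = TRUE)],
    config$n_updates, config$batch_size)
  mask_vec <- PARAM_GROUPS %in% unclass(mask)
  out <- .train_cpp(unclass(params),
                    aperm(trial_set$stimulus, c(2, 1, 3)),
                    aperm(trial_set$target, c(2, 1, 3)),
                    batch_idx, mask_vec,
                    config$learning_rate, config$beta1, config$beta2,
                    config$eps, config$grad_clip_norm, config$alpha,
                    config$beta, config$loss_start, config$precision)
  params_after <- params
  for (nm in PARAM_GROUPS[mask_vec]) {
    new <- out$params[[nm]]
    if (nm == "b_out") params_after[[nm]] <- as.numeric(new)
    else params_after[[nm]] <- matrix(new, nrow(params[[nm]]),
                                      ncol(params[[nm]]))
  }
  res <- list(params_before = params, params_after = params_after,
              loss_history = out$loss_history,
              error_history = out$rmse_history,
              mask = mask, config = config, task = task)
  class(res) <- "adaptation_result"
  res
}

#' @export
print.adaptation_result <- function(x, ...) {
  n <- length(x$loss_history)
  cat(sprintf("<adaptation_result> %s, %d updates", attr(x$mask, "hypothesis"),
              n))
  if (n > 0)
    cat(sprintf(", loss %.4g -> %.4g", x$loss_history[1], x$loss_history[n]))
  cat("\n")
  invisible(x)
}

#' Batched loss and gradients (double precision)
#'
#' Exposes the compiled forward/backward pass on an explicit batch of trials,
#' mainly for verification: the returned gradients can be compared against
#' finite differences of [compute_loss()] applied to [simulate_network()]
#' output, and the returned outputs against single-trial simulation.
#'
#' @param params `network_params`.
#' @param stimulus T x 3 x B array.
#' @param target T x 2 x B array.
#' @param config a [training_config()].
#' @return list with loss components, per-group `gradients`, and the batch
#'   `output` (T x 2 x B).
#' @export
network_gradients <- function(params, stimulus, target,
                              config = training_config()) {
  validate_params(params)
  res <- .loss_grad_cpp(unclass(params), aperm(stimulus, c(2, 1, 3)),
                        aperm(target, c(2, 1, 3)),
                        config$alpha, config$beta, config$loss_start)
  res$output <- aperm(res$output, c(2, 1, 3))
  res
}
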