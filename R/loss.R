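#' Training-loss configuration
#'
#' Hyperparameters of the regularized trajectory-tracking objective and its
#' Adam optimizer: squared output error averaged over the batch, both output
#' dimensions and the steps after `loss_start`, plus `alpha` times the sum of
#' the (unsquared) Frobenius norms of the eight weight matrices (the readout
#' bias is not regularized), plus `beta` times the mean squared tanh rate of
#' the three modules.
#'
#' @param learning_rate Adam learning rate.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param batch_size trials per update, sampled with replacement from the
#'   training split.
#' @param n_updates number of optimizer updates.
#' @param grad_clip_norm global gradient-norm clip applied to the trainable
#'   groups before each step.
#' @param alpha weight-regularizer coefficient.
#' @param beta rate-regularizer coefficient.
#' @param loss_start steps `> loss_start` enter the output-error term.
#' @param precision `"single"` (training default) or `"double"`.
#' @param seed RNG seed for batch sampling.
#' @return list of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8, batch_size = 80, n_updates = 500,
                            grad_clip_norm = 0.2, alpha = 0.001, beta = 0.8,
                            loss_start = 50, precision = c("single", "double"),
                            seed = 1) {
  precision <- match.arg(precision)
  stopifnot(learning_rate > 0, batch_size > 0, n_updates >= 0,
            grad_clip_norm > 0, alpha >= 0, beta >= 0, loss_start >= 0)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 eps = eps, batch_size = as.integer(batch_size),
                 n_updates = as.integer(n_updates),
                 grad_clip_norm = grad_clip_norm, alpha = alpha, beta = beta,
                 loss_start = as.integer(loss_start), precision = precision,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Training loss with components
#'
#' Reference R implementation of the training objective (the compiled
#' training core computes the same quantity). Accepts a single trial
#' (matrices) or a batch (arrays with a trailing batch dimension).
#'
#' @param output produced output, T x 2 or T x 2 x B.
#' @param target target trajectory, same shape.
#' @param params `network_params` (for the weight regularizer).
#' @param rates list with elements `up`, `pmd`, `m1`: tanh rates, T x N or
#'   T x N x B.
#' @param config a [training_config()]; only `alpha`, `beta`, `loss_start`
#'   are used.
#' @return list with `total`, `error`, `weights`, `rates` components.
#' @export
compute_loss <- function(output, target, params, rates,
                         config = training_config()) {
  if (length(dim(output)) == 2) output <- array(output, c(dim(output), 1))
  if (length(dim(target)) == 2) target <- array(target, c(dim(target), 1))
  if (!all(dim(output) == dim(target)))
    stop("output and target shapes differ")
  T_steps <- dim(output)[1]
  B <- dim(output)[3]
  ls <- config$loss_start
  if (ls >= T_steps) stop("loss_start must be below the trial length")
  err <- sum((output[(ls + 1):T_steps, , , drop = FALSE] -
              target[(ls + 1):T_steps, , , drop = FALSE])^2) /
    (B * (T_steps - ls) * 2)
  wmats <- c("W_in_up", "W_in_pmd", "W_out", "W_pmd", "W_m1", "W_pmd_m1",
             "W_up", "W_up_pmd")
  wreg <- config$alpha * sum(vapply(wmats, function(nm)
    sqrt(sum(params[[nm]]^2)), numeric(1)))
  r <- lapply(rates[c("up", "pmd", "m1")], function(m) {
    if (length(dim(m)) == 2) m <- array(m, c(dim(m), 1))
    if (dim(m)[1] != T_steps || dim(m)[3] != B)
      stop("rates shape inconsistent with output")
    m
  })
  N <- dim(r$up)[2]
  rreg <- config$beta * sum(r$up^2 + r$pmd^2 + r$m1^2) / (B * T_steps * N)
  list(total = err + wreg + rreg, error = err, weights = wreg, rates = rreg)
}
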