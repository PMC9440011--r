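PARAM_GROUPS <- c("W_up", "W_pmd", "W_m1", "W_up_pmd", "W_pmd_m1",
                  "W_in_up", "W_in_pmd", "W_out", "b_out")

#' Initialize network parameters
#'
#' Creates the nine parameter groups of the three-module rate network.
#' Recurrent (`W_up`, `W_pmd`, `W_m1`) and feedforward (`W_up_pmd`,
#' `W_pmd_m1`) weights are i.i.d. Gaussian with s.d. `recurrent_gain/sqrt(N)`
#' so the spectral radius of each recurrent matrix is close to
#' `recurrent_gain`; input weights have s.d. `input_scale`; the readout has
#' s.d. `1/sqrt(N)` and zero bias. Draw order is fixed, so a given seed gives
#' bit-identical parameters.
#'
#' @param N units per module.
#' @param seed integer RNG seed.
#' @param recurrent_gain s.d. scale of recurrent/feedforward weights.
#' @param input_scale s.d. of the input weights.
#' @param tau membrane time constant, seconds.
#' @param dt integration step, seconds; requires `0 < dt/tau <= 1`.
#' @return object of class `network_params`.
#' @export
init_params <- function(N = 400, seed = 1, recurrent_gain = 1.0,
                        input_scale = 0.1, tau = 0.05, dt = 0.01) {
  if (N < 1) stop("N must be >= 1")
  if (dt <= 0 || tau <= 0 || dt / tau > 1)
    stop("need 0 < dt/tau <= 1 for a stable Euler step")
  set.seed(seed)
  g <- recurrent_gain / sqrt(N)
  p <- list(
    W_up = matrix(rnorm(N * N, sd = g), N, N),
    W_pmd = matrix(rnorm(N * N, sd = g), N, N),
    W_m1 = matrix(rnorm(N * N, sd = g), N, N),
    W_up_pmd = matrix(rnorm(N * N, sd = g), N, N),
    W_pmd_m1 = matrix(rnorm(N * N, sd = g), N, N),
    W_in_up = matrix(rnorm(N * 3, sd = input_scale), N, 3),
    W_in_pmd = matrix(rnorm(N * 3, sd = input_scale), N, 3),
    W_out = matrix(rnorm(2 * N, sd = 1 / sqrt(N)), 2, N),
    b_out = c(0, 0),
    tau = tau, dt = dt, N = as.integer(N), seed = as.integer(seed))
  if (recurrent_gain == 0)
    for (nm in c("W_up", "W_pmd", "W_m1", "W_up_pmd", "W_pmd_m1"))
      p[[nm]][] <- 0
  class(p) <- "network_params"
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "network_params") || is.list(p))
  N <- nrow(p$W_up)
  for (nm in c("W_pmd", "W_m1", "W_up_pmd", "W_pmd_m1"))
    if (!all(dim(p[[nm]]) == c(N, N))) stop("inconsistent shape: ", nm)
  for (nm in c("W_in_up", "W_in_pmd"))
    if (!all(dim(p[[nm]]) == c(N, 3))) stop("inconsistent shape: ", nm)
  if (!all(dim(p$W_out) == c(2, N))) stop("inconsistent shape: W_out")
  if (length(p$b_out) != 2) stop("b_out must have length 2")
  if (p$dt <= 0 || p$tau <= 0 || p$dt / p$tau > 1)
    stop("need 0 < dt/tau <= 1")
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params> 3 modules x %d units, tau = %g s, dt = %g s\n",
    x$N, x$tau, x$dt))
  invisible(x)
}

#' Simulate the network on one trial
#'
#' Forward-Euler integration of the three-module leaky firing-rate dynamics:
#' each module's state decays at rate `dt/tau` and integrates the tanh rates
#' of its afferents. The upstream and PMd modules both receive the stimulus
#' through their own input matrices; M1 receives only PMd; the 2-D output is
#' a linear readout of the M1 rates plus a bias, recorded at every step.
#'
#' @param params `network_params`.
#' @param stimulus T x 3 stimulus matrix.
#' @param x0 optional initial state: list with `up`, `pmd`, `m1` N-vectors
#'   (default all-zero rest state).
#' @param rates if `TRUE` (default) include tanh rates in the result.
#' @return list of class `activity_record` with `x_up`, `x_pmd`, `x_m1`
#'   (T x N states), matching `r_*` rate matrices when `rates = TRUE`, and
#'   `output` (T x 2).
#' @export
simulate_network <- function(params, stimulus, x0 = NULL, rates = TRUE) {
  validate_params(params)
  if (ncol(stimulus) != 3) stop("stimulus must be T x 3")
  if (nrow(stimulus) < 1) stop("stimulus must have at least one step")
  res <- .sim_trial_cpp(unclass(params), t(stimulus), x0)
  rec <- list(x_up = t(res$x_up), x_pmd = t(res$x_pmd), x_m1 = t(res$x_m1),
              output = t(res$output))
  if (rates) {
    rec$r_up <- tanh(rec$x_up)
    rec$r_pmd <- tanh(rec$x_pmd)
    rec$r_m1 <- tanh(rec$x_m1)
  }
  class(rec) <- "activity_record"
  rec
}

#' Simulate the network on every trial of a set
#'
#' @param params `network_params`.
#' @param trial_set a `trial_set`.
#' @param rates include tanh rates per record.
#' @return list of `activity_record`s, one per trial.
#' @export
simulate_trial_set <- function(params, trial_set, rates = TRUE) {
  lapply(seq_len(trial_set$n_trials), function(i)
    simulate_network(params, trial_set$stimulus[, , i], rates = rates))
}

#' Save / load network parameters
#'
#' `write_network_params()` stores the parameter container with an exact
#' (bit-identical) round-trip; `read_network_params()` restores it.
#' `export_params_csv()` writes one CSV per parameter group for inspection.
#'
#' @param params `network_params`.
#' @param path file path (`.rds`) or, for the CSV export, a directory.
#' @return the read object, or the path invisibly.
#' @export
write_network_params <- function(params, path) {
  obj <- unclass(params)
  obj$.format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_network_params
#' @export
read_network_params <- function(path) {
  obj <- readRDS(path)
  obj$.format_version <- NULL
  class(obj) <- "network_params"
  validate_params(obj)
  obj
}

#' @rdname write_network_params
#' @export
export_params_csv <- function(params, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in PARAM_GROUPS)
    write.csv(as.matrix(params[[nm]]), file.path(path, paste0(nm, ".csv")),
              row.names = FALSE)
  invisible(path)
}
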