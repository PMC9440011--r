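# Small fixtures shared across tests. Everything is generated in code; the
# "toy" sizes keep single tests fast while exercising the full pipeline.

# trial configuration small enough for quick training tests: 1.2 s trials,
# short delays/movements so everything fits
toy_trial_config <- function(T_steps = 120) {
  trial_config(T_steps = T_steps, delay_range = c(0.3, 0.5),
               reaction_s = 0.1, movement_s = 0.4)
}

toy_params <- function(N = 6, seed = 42, ...) init_params(N, seed, ...)

# hand-specified 2-units-per-module network for exact-arithmetic oracles
tiny_params <- function(k_ratio = 0.2) {
  p <- list(
    W_up = matrix(c(0.5, -0.3, 0.2, 0.1), 2, 2),
    W_pmd = matrix(c(-0.2, 0.4, 0.3, -0.1), 2, 2),
    W_m1 = matrix(c(0.1, 0.2, -0.4, 0.3), 2, 2),
    W_up_pmd = matrix(c(0.6, -0.1, 0.05, 0.2), 2, 2),
    W_pmd_m1 = matrix(c(-0.3, 0.2, 0.1, 0.4), 2, 2),
    W_in_up = matrix(c(0.2, -0.1, 0.3, 0.05, -0.2, 0.1), 2, 3),
    W_in_pmd = matrix(c(-0.15, 0.25, 0.1, -0.05, 0.2, -0.3), 2, 3),
    W_out = matrix(c(0.4, -0.2, -0.1, 0.3), 2, 2),
    b_out = c(0.05, -0.02),
    tau = 0.05, dt = 0.05 * k_ratio, N = 2L)
  class(p) <- "network_params"
  p
}

zero_params <- function(N = 3, dt = 0.01, tau = 0.05) {
  p <- init_params(N, 1, recurrent_gain = 0, input_scale = 0, dt = dt,
                   tau = tau)
  p$W_in_up[] <- 0
  p$W_in_pmd[] <- 0
  p$W_out[] <- 0
  p
}
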