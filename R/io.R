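#' Save / load trial sets
#'
#' `write_trial_set()` persists a `trial_set` container (stimulus and target
#' arrays, go steps, ids, split, generator configuration) with an exact
#' round-trip; `export_trial_csv()` writes a single trial as a flat CSV
#' (step, stimulus, target trajectory, go flag) for inspection.
#'
#' @param trial_set a `trial_set`.
#' @param path destination file (`.rds` container, or `.csv` for the
#'   single-trial export).
#' @param trial trial index for the CSV export.
#' @return the read object, or the path invisibly.
#' @export
write_trial_set <- function(trial_set, path) {
  obj <- unclass(trial_set)
  obj$.format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(path) {
  obj <- readRDS(path)
  obj$.format_version <- NULL
  class(obj) <- "trial_set"
  obj
}

#' @rdname write_trial_set
#' @export
export_trial_csv <- function(trial_set, trial, path) {
  T_steps <- trial_set$config$T_steps
  df <- data.frame(step = seq_len(T_steps),
                   time_s = seq_len(T_steps) * trial_set$config$dt,
                   stim_x = trial_set$stimulus[, 1, trial],
                   stim_y = trial_set$stimulus[, 2, trial],
                   go_channel = trial_set$stimulus[, 3, trial],
                   target_x = trial_set$target[, 1, trial],
                   target_y = trial_set$target[, 2, trial])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
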