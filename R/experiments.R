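#' Scale profiles for the simulation campaigns
#'
#' The `"full"` profile mirrors the study conditions (400 units per module,
#' 4 s trials, 2238 trials, 500 de-novo + 100 adaptation updates) and takes
#' hours on one CPU. The `"reduced"` profile (150 units, 2 s trials, 320
#' trials, 300 + 100 updates) is the default for routine runs and preserves
#' every qualitative contrast; its delay range is capped at 1.1 s so the
#' reaction and movement windows fit inside the shorter trial.
#'
#' @param name `"reduced"` or `"full"`.
#' @return list with `N`, `T_steps`, `n_trials`, `n_updates_denovo`,
#'   `n_updates_adapt`, `batch_size`, `delay_range`, `go_eval_s`.
#' @export
scale_profile <- function(name = c("reduced", "full")) {
  name <- match.arg(name)
  switch(name,
    reduced = list(name = "reduced", N = 150L, T_steps = 200L,
                   n_trials = 320L, n_updates_denovo = 300L,
                   n_updates_adapt = 100L, batch_size = 80L,
                   delay_range = c(0.5, 1.1), go_eval_s = 1.0),
    full = list(name = "full", N = 400L, T_steps = 400L, n_trials = 2238L,
                n_updates_denovo = 500L, n_updates_adapt = 100L,
                batch_size = 80L, delay_range = c(0.5, 1.5),
                go_eval_s = 1.0))
}

#' Experiment configuration
#'
#' @param profile a [scale_profile()] name or list.
#' @param task `"vr"` (visuomotor rotation) or `"reassociation"`.
#' @param angles rotation angles in degrees (VR task).
#' @param hypotheses plasticity hypotheses to run: subset of `"H_input"`,
#'   `"H_local"`, `"input_remap"` (the last is training-free and only
#'   meaningful for the reassociation task).
#' @param n_seeds number of network initializations.
#' @param master_seed base seed; per-seed streams are derived by fixed
#'   offsets so adding seeds never changes existing ones.
#' @param noise_factor synaptic-fluctuation scale for the noise stage
#'   (`NULL` to skip).
#' @param precision training precision.
#' @param out_dir if non-NULL, persist per-seed artifacts there.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(profile = "reduced", task = c("vr", "reassociation"),
                              angles = 30, hypotheses = c("H_input", "H_local"),
                              n_seeds = 10, master_seed = 1,
                              noise_factor = NULL,
                              precision = "single", out_dir = NULL) {
  task <- match.arg(task)
  if (is.character(profile)) profile <- scale_profile(profile)
  stopifnot(n_seeds >= 1)
  structure(list(profile = profile, task = task, angles = angles,
                 hypotheses = hypotheses, n_seeds = as.integer(n_seeds),
                 master_seed = as.integer(master_seed),
                 noise_factor = noise_factor, precision = precision,
                 out_dir = out_dir),
            class = "experiment_config")
}

# fixed-offset seed streams: adding seeds or streams never disturbs others
derive_seed <- function(master, seed_index, stream = 0) {
  as.integer((abs(master) + 7919 * seed_index + 104729 * stream) %%
               2147483647L + 1L)
}

trial_config_for <- function(profile) {
  trial_config(T_steps = profile$T_steps, delay_range = profile$delay_range,
               reaction_s = profile$reaction_s %||% 0.15,
               movement_s = profile$movement_s %||% 0.7)
}

adapt_and_measure <- function(denovo, baseline_eval, pert_set, pert_eval_set,
                              hypothesis, cfg, seed_i, task_label) {
  prof <- cfg$profile
  if (hypothesis == "input_remap") {
    perm <- attr(pert_set, "reassociation")
    if (is.null(perm))
      stop("input_remap requires a reassociation task")
    params_after <- input_remap(denovo$params_after, perm,
                                pert_set$targets)
    result <- list(params_before = denovo$params_after,
                   params_after = params_after,
                   loss_history = numeric(0), error_history = numeric(0),
                   mask = plasticity_mask("custom",
                                          c("W_in_up", "W_in_pmd")),
                   config = NULL, task = task_label)
    class(result) <- "adaptation_result"
  } else {
    mask <- plasticity_mask(hypothesis)
    tc <- training_config(batch_size = prof$batch_size,
                          n_updates = prof$n_updates_adapt,
                          precision = cfg$precision,
                          seed = derive_seed(cfg$master_seed, seed_i, 3))
    result <- train_network(denovo$params_after, pert_set, mask, tc,
                            task = task_label)
  }
  late_eval <- evaluate_network(result$params_after, pert_eval_set)
  unadapted_eval <- evaluate_network(denovo$params_after, pert_eval_set)
  ch <- epoch_changes(baseline_eval, late_eval)
  wc <- weight_change_summary(result$params_before, result$params_after,
                              groups = intersect(unclass(result$mask),
                                                 setdiff(PARAM_GROUPS, "b_out")))
  list(result = result, late_eval = late_eval,
       unadapted_eval = unadapted_eval, changes = ch, weights = wc)
}

#' Run an adaptation campaign
#'
#' For every seed: generate the trial corpus, initialize and de-novo train
#' the network, evaluate the baseline on canonical-go trials, apply the
#' configured perturbation(s), adapt under each hypothesis, re-evaluate, and
#' compute all metrics. A failing seed is recorded and the remaining seeds
#' continue. Re-running with the same configuration reproduces the report
#' exactly.
#'
#' @param cfg an [experiment_config()].
#' @return list of class `experiment_report`: `metrics` (long data.frame:
#'   seed, hypothesis, task, module/group, metric, value), `seeds` (per-seed
#'   detail), `errors`, `config`.
#' @export
run_adaptation_experiment <- function(cfg) {
  prof <- cfg$profile
  tconf <- trial_config_for(prof)
  rows <- list()
  seed_detail <- list()
  errors <- list()
  add_row <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)
  for (i in seq_len(cfg$n_seeds)) {
    res <- tryCatch({
      ts <- generate_trial_set(prof$n_trials, derive_seed(cfg$master_seed, i, 0),
                               tconf)
      p0 <- init_params(prof$N, derive_seed(cfg$master_seed, i, 1))
      denovo <- train_network(
        p0, ts, plasticity_mask("de_novo"),
        training_config(batch_size = prof$batch_size,
                        n_updates = prof$n_updates_denovo,
                        precision = cfg$precision,
                        seed = derive_seed(cfg$master_seed, i, 2)),
        task = "de_novo")
      eval_set <- make_eval_set(tconf, prof$go_eval_s)
      baseline_eval <- evaluate_network(denovo$params_after, eval_set)
      test_set <- subset_trial_set(ts, which(ts$split == "test"))
      baseline_test <- evaluate_network(denovo$params_after, test_set,
                                        window_s = NULL)
      detail <- list(trial_set_seed = ts$seed, denovo = denovo,
                     baseline_eval = baseline_eval,
                     baseline_test_rmse = baseline_test$rmse, runs = list())
      perturbations <- if (cfg$task == "vr") {
        lapply(cfg$angles, function(a) list(
          label = paste0("vr", a),
          train = apply_vr(ts, a), eval = apply_vr(eval_set, a)))
      } else {
        perm <- random_derangement(tconf$n_targets,
                                   derive_seed(cfg$master_seed, i, 4))
        list(list(label = "reassociation",
                  train = apply_reassociation(ts, perm),
                  eval = apply_reassociation(eval_set, perm)))
      }
      for (pert in perturbations) {
        for (hyp in cfg$hypotheses) {
          run <- adapt_and_measure(denovo, baseline_eval, pert$train,
                                   pert$eval, hyp, cfg, i, pert$label)
          key <- paste(hyp, pert$label, sep = ".")
          detail$runs[[key]] <- run
          for (j in seq_len(nrow(run$changes))) {
            add_row(seed = i, hypothesis = hyp, task = pert$label,
                    unit = run$changes$module[j], metric = "activity_change",
                    value = run$changes$activity_change[j])
            add_row(seed = i, hypothesis = hyp, task = pert$label,
                    unit = run$changes$module[j],
                    metric = "covariance_change",
                    value = run$changes$covariance_change[j])
          }
          for (j in seq_len(nrow(run$weights))) {
            add_row(seed = i, hypothesis = hyp, task = pert$label,
                    unit = run$weights$group[j], metric = "weight_change",
                    value = run$weights$weight_change[j])
            add_row(seed = i, hypothesis = hyp, task = pert$label,
                    unit = run$weights$group[j], metric = "dimensionality",
                    value = run$weights$dimensionality[j])
          }
          add_row(seed = i, hypothesis = hyp, task = pert$label,
                  unit = "behaviour", metric = "rmse",
                  value = run$late_eval$rmse)
          add_row(seed = i, hypothesis = hyp, task = pert$label,
                  unit = "behaviour", metric = "rmse_unadapted",
                  value = run$unadapted_eval$rmse)
          add_row(seed = i, hypothesis = hyp, task = pert$label,
                  unit = "behaviour", metric = "rmse_ratio_vs_baseline",
                  value = run$late_eval$rmse / baseline_test$rmse)
          if (!is.null(cfg$noise_factor) && hyp != "input_remap") {
            noisy <- add_synaptic_fluctuation(
              run$result, cfg$noise_factor,
              seed = derive_seed(cfg$master_seed, i, 5))
            noisy_eval <- evaluate_network(noisy, pert$eval,
                                           window_s = NULL)
            add_row(seed = i, hypothesis = hyp, task = pert$label,
                    unit = "behaviour", metric = "rmse_noise",
                    value = noisy_eval$rmse)
            for (nm in unclass(run$result$mask)) {
              if (nm == "b_out") next
              add_row(seed = i, hypothesis = hyp, task = pert$label,
                      unit = nm, metric = "dimensionality_noise",
                      value = participation_ratio(
                        noisy[[nm]] - run$result$params_before[[nm]]))
            }
          }
        }
      }
      detail
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <-
        list(seed = i, message = conditionMessage(res))
    } else {
      seed_detail[[paste0("seed", i)]] <- res
      if (!is.null(cfg$out_dir)) {
        dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_network_params(
          res$denovo$params_after,
          file.path(cfg$out_dir, sprintf("denovo_seed%03d.rds", i)))
        for (key in names(res$runs))
          write_network_params(
            res$runs[[key]]$result$params_after,
            file.path(cfg$out_dir, sprintf("%s_seed%03d.rds", key, i)))
      }
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = integer(), hypothesis = character(),
               task = character(), unit = character(), metric = character(),
               value = numeric())
  report <- structure(list(metrics = metrics, seeds = seed_detail,
                           errors = errors, config = cfg),
                      class = "experiment_report")
  if (!is.null(cfg$out_dir)) {
    write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
              row.names = FALSE)
    saveRDS(cfg, file.path(cfg$out_dir, "config.rds"))
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d seeds, %d metric rows, %d failed seeds\n",
              length(x$seeds), nrow(x$metrics), length(x$errors)))
  invisible(x)
}

#' Side-by-side hypothesis comparison
#'
#' Aggregates an experiment report across seeds (median) and tabulates the
#' per-hypothesis activity change (PMd vs M1), covariance change, weight
#' change and dimensionality, flagging the diagnostic signatures: larger M1
#' than PMd activity change (the local-plasticity fingerprint) and
#' near-zero covariance change (the input-reassociation fingerprint).
#'
#' @param report an `experiment_report`, or a list of them sharing seeds.
#' @return data.frame, one row per hypothesis x task, with signature flags.
#' @export
hypothesis_comparison <- function(report) {
  reports <- if (inherits(report, "experiment_report")) list(report) else report
  seed_sets <- lapply(reports, function(r) sort(unique(r$metrics$seed)))
  if (length(unique(vapply(seed_sets, paste, character(1), collapse = ","))) > 1)
    stop("reports evaluated on different seed sets")
  m <- do.call(rbind, lapply(reports, `[[`, "metrics"))
  if (nrow(m) == 0) stop("empty report")
  combos <- unique(m[, c("hypothesis", "task")])
  get <- function(hyp, task, metric, unit) {
    v <- m$value[m$hypothesis == hyp & m$task == task &
                 m$metric == metric & m$unit == unit]
    if (length(v)) median(v) else NA_real_
  }
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    hyp <- combos$hypothesis[i]
    task <- combos$task[i]
    act_pmd <- get(hyp, task, "activity_change", "pmd")
    act_m1 <- get(hyp, task, "activity_change", "m1")
    cov_pmd <- get(hyp, task, "covariance_change", "pmd")
    cov_m1 <- get(hyp, task, "covariance_change", "m1")
    wc <- m$value[m$hypothesis == hyp & m$task == task &
                  m$metric == "weight_change"]
    data.frame(hypothesis = hyp, task = task,
               activity_change_pmd = act_pmd, activity_change_m1 = act_m1,
               covariance_change_pmd = cov_pmd, covariance_change_m1 = cov_m1,
               weight_change_median = if (length(wc)) median(wc) else NA_real_,
               rmse = get(hyp, task, "rmse", "behaviour"),
               flag_m1_gt_pmd_activity = isTRUE(act_m1 > act_pmd),
               flag_covariance_preserved = isTRUE(
                 max(cov_pmd, cov_m1) < 1e-6))
  }))
  out
}
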