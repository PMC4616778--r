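#' Configuration for the end-to-end analysis pipeline
#'
#' Collects the stage parameters of the full run: waveform simulation,
#' beat extraction, index computation, cohort simulation and cohort
#' analysis. Re-running with the same configuration reproduces every
#' output byte-for-byte; the configuration snapshot is written alongside
#' the outputs for provenance.
#'
#' @param seed Integer master seed for all stochastic stages.
#' @param n_patients Cohort size (default 39).
#' @param cohort Optional list of overrides passed to [cohort_sim_config()].
#' @param waveform Optional list of overrides passed to
#'   [waveform_sim_config()] for the demonstration waveform stage; must
#'   include `resp_rate` (directly or by default).
#' @param score_var Variable whose cut-off table is exported (default
#'   `"ea"`).
#' @param roc_vars T2 variables evaluated by ROC analysis.
#' @param verbose Print progress lines.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_patients = 39,
                            cohort = list(), waveform = list(),
                            score_var = "ea",
                            roc_vars = c("ea", "ppv", "svv", "map",
                                         "stroke_volume_index", "hr"),
                            verbose = FALSE) {
  stopifnot(is.list(cohort), is.list(waveform))
  required <- c("seed", "n_patients", "score_var")
  cfg <- list(seed = as.integer(seed), n_patients = n_patients,
              cohort = cohort, waveform = waveform,
              score_var = score_var, roc_vars = roc_vars,
              verbose = isTRUE(verbose))
  for (f in required)
    if (is.null(cfg[[f]]) || length(cfg[[f]]) != 1 || is.na(cfg[[f]]))
      stop(sprintf("pipeline configuration field '%s' is missing or invalid", f))
  wf_args <- utils::modifyList(list(seed = cfg$seed), waveform)
  wf_cfg <- tryCatch(do.call(waveform_sim_config, wf_args),
                     error = function(e)
                       stop(sprintf("waveform stage configuration invalid: %s",
                                    conditionMessage(e)), call. = FALSE))
  if (is.null(wf_cfg$resp_rate) || !is.finite(wf_cfg$resp_rate))
    stop("waveform stage configuration field 'resp_rate' is missing")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Executes simulate -> extract-beats -> compute-indices on a
#' demonstration waveform, then simulate-cohort -> analyze on a synthetic
#' cohort, writing all tables, a run log and the configuration snapshot to
#' `out_dir`. Outputs are deterministic given the configuration seed.
#'
#' Files written: `waveform.csv` (+ `.json` sidecar), `beats.csv`,
#' `indices.csv`, `cohort.csv`, `group_comparison.csv` (per-variable T2
#' comparison between responders and nonresponders), `anova_map.csv`
#' (group x time repeated-measures ANOVA of MAP), `roc_summary.csv` (AUC
#' with DeLong CI per variable), `cutoff_table.csv` (cut-off /
#' sensitivity / specificity table for the score variable),
#' `run_config.json` and `log.txt`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed objects and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (config$verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- waveform demonstration: simulate -> extract-beats -> compute-indices
  wf_cfg <- do.call(waveform_sim_config,
                    utils::modifyList(list(seed = config$seed), config$waveform))
  wf <- stage("simulate", simulate_waveform(wf_cfg))
  say("simulate: %d samples at %g Hz (HR %g, RR %g)",
      length(wf$pressure), wf$sampling_rate, wf$heart_rate, wf$resp_rate)
  beats <- stage("extract-beats", {
    b <- detect_beats(wf)
    estimate_stroke_volume(b, calibration_k = 1)
  })
  say("extract-beats: %d beats", nrow(beats))
  idx <- stage("compute-indices", {
    cyc <- segment_respiratory_cycles(beats)
    ppv <- compute_ppv(beats, cyc)
    svv <- compute_svv(beats, cyc)
    ea_series(ppv, svv)
  })
  say("compute-indices: %d SVV readings, Ea at t=%g s: %.3f",
      nrow(idx), max(idx$time_s), utils::tail(idx$ea, 1))

  # --- cohort: simulate -> analyze
  coh_cfg <- do.call(cohort_sim_config,
                     utils::modifyList(list(seed = config$seed,
                                            n_patients = config$n_patients),
                                       config$cohort))
  cohort <- stage("simulate-cohort", simulate_cohort(coh_cfg))
  resp <- cohort_responders(cohort)
  say("simulate-cohort: %d patients, %d responders / %d nonresponders",
      coh_cfg$n_patients, sum(resp$responder), sum(!resp$responder))

  t2 <- cohort[cohort$timepoint == "T2", ]
  t2 <- t2[match(resp$patient_id, t2$patient_id), ]
  labels <- resp$responder

  cmp <- stage("analyze", {
    rows <- lapply(config$roc_vars, function(v) {
      gc <- compare_groups(t2[[v]], labels, "continuous", variable = v)
      data.frame(variable = v, test_used = gc$test_used,
                 statistic = gc$statistic, p_value = gc$p_value,
                 mean_responder = gc$summary$mean[1],
                 mean_nonresponder = gc$summary$mean[2])
    })
    do.call(rbind, rows)
  })

  anova_tab <- stage("analyze", {
    long <- cohort[, c("patient_id", "timepoint", "map")]
    long$group <- resp$responder[match(long$patient_id, resp$patient_id)]
    rm_anova_two_way(long, value = "map", subject = "patient_id",
                     group = "group", time = "timepoint")
  })

  roc_tab <- stage("analyze", {
    rows <- lapply(config$roc_vars, function(v) {
      r <- roc_analysis(t2[[v]], labels)
      data.frame(variable = v, auc = r$auc, ci_low = r$auc_ci[1],
                 ci_high = r$auc_ci[2], p_value = r$p_value,
                 youden_cutoff = r$youden_cutoff, youden_j = r$youden_j)
    })
    do.call(rbind, rows)
  })
  roc_score <- roc_analysis(t2[[config$score_var]], labels)
  say("analyze: %s AUC %.3f (95%% CI %.3f-%.3f), Youden cut-off > %.3g",
      config$score_var, roc_score$auc, roc_score$auc_ci[1],
      roc_score$auc_ci[2], roc_score$youden_cutoff)

  paths <- list(
    waveform = file.path(out_dir, "waveform.csv"),
    beats = file.path(out_dir, "beats.csv"),
    indices = file.path(out_dir, "indices.csv"),
    cohort = file.path(out_dir, "cohort.csv"),
    group_comparison = file.path(out_dir, "group_comparison.csv"),
    anova = file.path(out_dir, "anova_map.csv"),
    roc = file.path(out_dir, "roc_summary.csv"),
    cutoffs = file.path(out_dir, "cutoff_table.csv"),
    config = file.path(out_dir, "run_config.json"),
    log = file.path(out_dir, "log.txt"))

  write_waveform_csv(wf, paths$waveform)
  write_beats_csv(beats, paths$beats)
  utils::write.csv(idx, paths$indices, row.names = FALSE)
  write_cohort_csv(cohort, paths$cohort)
  utils::write.csv(cmp, paths$group_comparison, row.names = FALSE)
  utils::write.csv(anova_tab, paths$anova, row.names = FALSE)
  utils::write.csv(roc_tab, paths$roc, row.names = FALSE)
  utils::write.csv(roc_score$cutoff_table, paths$cutoffs, row.names = FALSE)
  jsonlite::write_json(unclass(config), paths$config,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, paths$log)

  invisible(list(waveform = wf, beats = beats, indices = idx,
                 cohort = cohort, responders = resp,
                 group_comparison = cmp, anova = anova_tab,
                 roc_summary = roc_tab, roc_score = roc_score,
                 paths = paths))
}
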