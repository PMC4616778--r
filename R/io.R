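#' Read and write arterial waveforms as CSV with a JSON sidecar
#'
#' Waveforms travel as a two-column CSV (`time_s`, `pressure_mmhg`) plus a
#' JSON sidecar (`<path>.json`) holding the acquisition metadata
#' (`sampling_rate`, `resp_rate`, `heart_rate`) and, for simulated traces,
#' the analytic `ground_truth`.
#'
#' @param waveform A `waveform_record`.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_waveform_csv` returns `path` invisibly;
#'   `read_waveform_csv` returns a `waveform_record`.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(
    data.frame(time_s = waveform$time, pressure_mmhg = waveform$pressure),
    path, row.names = FALSE)
  meta <- list(sampling_rate = waveform$sampling_rate,
               resp_rate = waveform$resp_rate,
               heart_rate = waveform$heart_rate,
               ground_truth = waveform$ground_truth)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param resp_rate,sampling_rate Metadata overrides when no sidecar file
#'   exists; `sampling_rate` defaults to the inverse median time step.
#' @export
read_waveform_csv <- function(path, resp_rate = NULL, sampling_rate = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "pressure_mmhg") %in% names(d)))
    stop("waveform CSV must have columns time_s, pressure_mmhg")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  sr <- sampling_rate %||% meta$sampling_rate %||% (1 / stats::median(diff(d$time_s)))
  rr <- resp_rate %||% meta$resp_rate
  structure(list(time = d$time_s, pressure = d$pressure_mmhg,
                 sampling_rate = sr, resp_rate = rr,
                 heart_rate = meta$heart_rate,
                 ground_truth = meta$ground_truth),
            class = "waveform_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write cohort tables
#'
#' Cohorts are long-format CSVs with one row per patient per time point and
#' columns `patient_id`, `timepoint` (T1-T4), `map`, `sbp`, `hr`,
#' `cardiac_index`, `stroke_volume_index`, `svv`, `ppv`, `ea`.
#'
#' @param cohort A cohort data frame.
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("patient_id", "timepoint", "map")
  if (!all(need %in% names(d)))
    stop("cohort CSV must have at least columns patient_id, timepoint, map")
  d
}

#' Write a beat table as CSV
#'
#' One row per detected beat: `foot_time_s`, `sbp`, `dbp`, `pp`,
#' `systolic_area` and, when present, `sv_estimate`.
#'
#' @param beats A `beat_series`.
#' @param path CSV file path.
#' @export
write_beats_csv <- function(beats, path) {
  cols <- intersect(c("foot_time", "sbp", "dbp", "pp", "systolic_area",
                      "sv_estimate", "map", "period_s", "flagged"),
                    names(beats))
  d <- as.data.frame(beats)[, cols]
  names(d)[names(d) == "foot_time"] <- "foot_time_s"
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
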