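#' Pulse pressure variation on the monitor's 8-s epoch grid
#'
#' For each complete respiratory cycle the per-cycle variation is
#' `PPV = 100 * 2 * (PP_max - PP_min) / (PP_max + PP_min)`, where the
#' extremes are taken over the beats of that cycle. Cycle values are
#' averaged within consecutive 8-s epochs (a cycle belongs to the epoch
#' containing its midpoint), and each reported reading is the mean of 4
#' consecutive epochs, rolling with a stride of one epoch — the update
#' convention of bedside monitors that refresh PPV every 8 s.
#'
#' @param beats A `beat_series` from [detect_beats()].
#' @param cycles Respiratory windows from [segment_respiratory_cycles()].
#' @param epoch_s Epoch length in seconds (default 8).
#' @param n_epochs_avg Number of consecutive epochs averaged per reading
#'   (default 4).
#' @return Data frame `time_s` (end of the averaging span), `ppv` (%).
#' @export
compute_ppv <- function(beats, cycles, epoch_s = 8, n_epochs_avg = 4) {
  cyc <- .cycle_values(beats, cycles, function(b) {
    pmax <- max(b$pp); pmin <- min(b$pp)
    100 * 2 * (pmax - pmin) / (pmax + pmin)
  })
  .epoch_readings(cyc, epoch_s, n_epochs_avg, "PPV")
}

#' Stroke volume variation on the monitor's 20-s window grid
#'
#' For each complete respiratory cycle the per-cycle variation is
#' `SVV = 100 * (SV_max - SV_min) / SV_mean` over the stroke-volume
#' estimates of that cycle's beats; the reported value for each 20-s
#' window is the mean over the cycles whose midpoint falls in the window
#' — the update convention of pulse-contour monitors that refresh SVV
#' every 20 s. The result is invariant to the stroke-volume calibration
#' constant.
#'
#' @param beats A `beat_series` carrying an `sv_estimate` column (see
#'   [estimate_stroke_volume()]).
#' @param cycles Respiratory windows from [segment_respiratory_cycles()].
#' @param window_s Reporting window in seconds (default 20).
#' @return Data frame `time_s` (window end), `svv` (%).
#' @export
compute_svv <- function(beats, cycles, window_s = 20) {
  if (is.null(beats$sv_estimate))
    stop("beats must carry sv_estimate; call estimate_stroke_volume() first")
  cyc <- .cycle_values(beats, cycles, function(b) {
    100 * (max(b$sv_estimate) - min(b$sv_estimate)) / mean(b$sv_estimate)
  })
  n_win <- floor(max(cycles$windows$t_end) / window_s)
  if (n_win < 1) stop("trace shorter than one SVV window")
  out <- data.frame(time_s = numeric(0), svv = numeric(0))
  for (w in seq_len(n_win)) {
    inw <- cyc$t_mid >= (w - 1) * window_s & cyc$t_mid < w * window_s
    if (!any(inw)) {
      warning(sprintf("SVV window %d (%g-%g s) has no complete respiratory cycle; skipped",
                      w, (w - 1) * window_s, w * window_s))
      next
    }
    out <- rbind(out, data.frame(time_s = w * window_s,
                                 svv = mean(cyc$value[inw])))
  }
  out
}

# per-cycle statistic over complete cycles, with unflagged beats
.cycle_values <- function(beats, cycles, fun) {
  stopifnot(inherits(cycles, "resp_windows"))
  win <- cycles$windows
  keep <- which(win$complete)
  t_mid <- numeric(0); value <- numeric(0)
  for (w in keep) {
    b <- beats[cycles$beat_index[[w]], , drop = FALSE]
    b <- b[!b$flagged, , drop = FALSE]
    if (nrow(b) < 2) next
    t_mid <- c(t_mid, win$t_mid[w])
    value <- c(value, fun(b))
  }
  list(t_mid = t_mid, value = value)
}

.epoch_readings <- function(cyc, epoch_s, n_avg, what) {
  if (length(cyc$value) == 0) stop(sprintf("no complete respiratory cycle for %s", what))
  n_epoch <- floor(max(cyc$t_mid) / epoch_s) + 1L
  epoch_val <- rep(NA_real_, n_epoch)
  for (e in seq_len(n_epoch)) {
    ine <- cyc$t_mid >= (e - 1) * epoch_s & cyc$t_mid < e * epoch_s
    if (!any(ine)) {
      warning(sprintf("%s epoch %d (%g-%g s) has no complete respiratory cycle; skipped",
                      what, e, (e - 1) * epoch_s, e * epoch_s))
      next
    }
    epoch_val[e] <- mean(cyc$value[ine])
  }
  usable <- which(!is.na(epoch_val))
  if (length(usable) < n_avg)
    stop(sprintf("fewer than %d usable %g-s epochs for %s", n_avg, epoch_s, what))
  out <- data.frame(time_s = numeric(0), value = numeric(0))
  for (e in seq_len(n_epoch - n_avg + 1L)) {
    span <- e:(e + n_avg - 1L)
    if (any(is.na(epoch_val[span]))) next
    out <- rbind(out, data.frame(time_s = (e + n_avg - 1L) * epoch_s,
                                 value = mean(epoch_val[span])))
  }
  names(out) <- c("time_s", tolower(what))
  out
}

#' Dynamic arterial elastance at a time point
#'
#' Dynamic arterial elastance is the PPV/SVV ratio. Following the bedside
#' measurement convention, it is computed from the average of the 3
#' consecutive readings of each index at or before the requested time:
#' `Ea = mean(last 3 PPV) / mean(last 3 SVV)` (a ratio of averages). The
#' two indices live on different update grids (8 s vs 20 s); averaging 3
#' consecutive readings of each makes the residual time offset immaterial.
#'
#' @param ppv_readings Data frame `time_s`, `ppv` from [compute_ppv()].
#' @param svv_readings Data frame `time_s`, `svv` from [compute_svv()].
#' @param at_time Time point (s) at which Ea is requested.
#' @param n_readings Number of consecutive readings averaged (default 3).
#' @return Dynamic arterial elastance (dimensionless scalar).
#' @export
compute_dynamic_ea <- function(ppv_readings, svv_readings, at_time,
                               n_readings = 3) {
  pv <- ppv_readings$ppv[ppv_readings$time_s <= at_time]
  sv <- svv_readings$svv[svv_readings$time_s <= at_time]
  if (length(pv) < n_readings || length(sv) < n_readings)
    stop(sprintf("need %d readings of PPV and SVV at or before t = %g s",
                 n_readings, at_time))
  pv <- utils::tail(pv, n_readings)
  sv <- utils::tail(sv, n_readings)
  if (mean(sv) == 0) stop("SVV zero; Ea undefined")
  mean(pv) / mean(sv)
}

#' Paired index series with dynamic arterial elastance
#'
#' Pairs each SVV reading with the nearest-in-time PPV reading and forms
#' the Ea series from 3 consecutive paired readings (ratio of averages),
#' reported at the time of the later reading in each triplet.
#'
#' @inheritParams compute_dynamic_ea
#' @return Data frame `time_s`, `ppv`, `svv`, `ea` (Ea is `NA` until 3
#'   paired readings have accrued).
#' @export
ea_series <- function(ppv_readings, svv_readings, n_readings = 3) {
  if (nrow(svv_readings) == 0) stop("empty SVV series")
  pair_ppv <- vapply(svv_readings$time_s, function(t0)
    ppv_readings$ppv[which.min(abs(ppv_readings$time_s - t0))], numeric(1))
  n <- nrow(svv_readings)
  ea <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i < n_readings) next
    span <- (i - n_readings + 1L):i
    ms <- mean(svv_readings$svv[span])
    if (ms > 0) ea[i] <- mean(pair_ppv[span]) / ms
  }
  data.frame(time_s = svv_readings$time_s, ppv = pair_ppv,
             svv = svv_readings$svv, ea = ea)
}

#' Classify arterial pressure responders to a fluid challenge
#'
#' A patient is an arterial pressure responder when mean arterial pressure
#' rises by at least 15% after the fluid challenge; the boundary is
#' inclusive (an increase of exactly 15.0% is a responder).
#'
#' @param map_before MAP before the fluid challenge, mmHg (vectorized).
#' @param map_after MAP after the fluid challenge, mmHg.
#' @param threshold_pct Response threshold in percent (default 15).
#' @return Logical vector: `TRUE` for responders.
#' @examples
#' classify_responder(60, c(69, 68, 70))  # TRUE FALSE TRUE
#' @export
classify_responder <- function(map_before, map_after, threshold_pct = 15) {
  if (any(map_before <= 0) || any(map_after <= 0))
    stop("MAP values must be positive")
  # 1e-9 relative guard so a MAP pair constructed to sit exactly on the
  # boundary classifies as a responder despite floating-point round-off
  100 * (map_after - map_before) / map_before >= threshold_pct * (1 - 1e-9)
}

#' Check the preload-dependence and hypotension gate
#'
#' The fluid-challenge protocol requires a preload-dependent state —
#' SVV strictly above 10% sustained over the trailing 10 minutes — together
#' with arterial hypotension: MAP below 65 mmHg or systolic pressure below
#' 90 mmHg. All inequalities are strict, as printed on protocol sheets.
#'
#' @param svv_readings Data frame `time_s`, `svv` spanning at least
#'   `window_min` minutes.
#' @param map Current mean arterial pressure, mmHg.
#' @param sbp Current systolic arterial pressure, mmHg.
#' @param svv_threshold SVV threshold in percent (default 10).
#' @param window_min Sustainment window in minutes (default 10).
#' @param map_threshold,sbp_threshold Hypotension thresholds, mmHg
#'   (defaults 65 and 90).
#' @return `TRUE` when the gate is satisfied.
#' @export
check_preload_dependency <- function(svv_readings, map, sbp,
                                     svv_threshold = 10, window_min = 10,
                                     map_threshold = 65, sbp_threshold = 90) {
  t <- svv_readings$time_s
  if (length(t) == 0 || max(t) - min(t) < window_min * 60)
    stop(sprintf("insufficient history: SVV readings must span >= %g min", window_min))
  recent <- svv_readings$svv[t >= max(t) - window_min * 60]
  all(recent > svv_threshold) && (map < map_threshold || sbp < sbp_threshold)
}
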