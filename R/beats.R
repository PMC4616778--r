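#' Detect cardiac beats in an arterial pressure trace
#'
#' Segments a uniformly sampled arterial pressure waveform into beats and
#' extracts per-beat landmarks: diastolic foot, systolic peak, dicrotic
#' notch (when detectable), pulse pressure, systolic area and beat-mean
#' pressure.
#'
#' Beat onsets are found from the maximal systolic upstroke: samples whose
#' (lightly smoothed) slope exceeds 30% of the trace's 95th-percentile
#' positive slope mark upstrokes; the foot is the pressure minimum in the
#' short window preceding each upstroke, the peak the maximum before the
#' next foot. The dicrotic notch is the first local minimum after the peak
#' that has fallen below half the pulse amplitude; if none is detectable,
#' systole is taken to end at a fixed 0.35 fraction of the instantaneous
#' beat period. The systolic area is the trapezoidal integral of pressure
#' above the diastolic foot from foot to systole end, in mmHg*s. Beats
#' touching the trace boundaries are discarded; detected intervals whose
#' pulse amplitude falls below 40% of the median (spurious sub-beats, e.g.
#' a dicrotic wave crossing the slope threshold under noise) are merged
#' into their predecessor. Beats whose instantaneous rate falls outside
#' 20-250 beats/min are kept but flagged.
#'
#' @param waveform A `waveform_record` (see [simulate_waveform()] or
#'   [read_waveform_csv()]), or any list with elements `pressure`,
#'   `sampling_rate` and `resp_rate`.
#' @param smooth_ms Width of the moving-average pre-smoother used for
#'   landmark detection, in milliseconds (default 40; 0 disables).
#' @return An object of class `beat_series`: a data frame with one row per
#'   beat (`foot_index`, `peak_index`, `notch_index`, `foot_time`, `sbp`,
#'   `dbp`, `pp`, `systolic_area`, `map`, `period_s`, `flagged`) carrying
#'   `sampling_rate` and `resp_rate` attributes.
#' @export
detect_beats <- function(waveform, smooth_ms = 40) {
  p <- waveform$pressure
  fs <- waveform$sampling_rate
  if (is.null(p) || is.null(fs)) stop("waveform must carry pressure and sampling_rate")
  if (fs < 25) stop("sampling rate too low (< 25 Hz)")
  if (any(!is.finite(p))) stop("pressure trace contains non-finite values")
  if (diff(range(p)) < 1) stop("no pulsatile signal (pressure range < 1 mmHg)")

  w <- max(1L, round(smooth_ms / 1000 * fs))
  ps <- if (w > 1) stats::filter(p, rep(1 / w, w), sides = 2) else p
  ps <- as.numeric(ps)
  # moving average leaves NAs at the edges; pad with raw samples
  na <- is.na(ps)
  ps[na] <- p[na]

  slope <- diff(ps) * fs
  pos <- slope[slope > 0]
  if (length(pos) == 0) stop("no pulsatile signal (no rising pressure)")
  thr <- 0.30 * stats::quantile(pos, 0.95, names = FALSE)
  up <- slope > thr

  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(seg) < 2) stop("fewer than 2 beats detected")
  # merge upstroke fragments separated by less than a quarter beat
  gap_merge <- 0.25 * stats::median(diff(seg$start))
  keep <- c(TRUE, diff(seg$start) > gap_merge)
  merged_start <- seg$start[keep]
  merged_end <- numeric(sum(keep))
  gi <- cumsum(keep)
  for (g in seq_len(max(gi))) merged_end[g] <- max(seg$end[gi == g])
  seg <- data.frame(start = merged_start, end = merged_end)

  n_up <- nrow(seg)
  look <- round(0.25 * stats::median(diff(seg$start)))
  foot <- integer(n_up)
  for (k in seq_len(n_up)) {
    lo <- max(1L, seg$start[k] - look)
    win <- ps[lo:seg$start[k]]
    # last index attaining the minimum: the sample adjacent to the upstroke
    foot[k] <- lo + max(which(win == min(win))) - 1L
  }
  # drop upstrokes whose search window hits the trace start, and the last
  # upstroke (no closing foot): boundary beats are discarded
  valid <- foot > look
  seg <- seg[valid, , drop = FALSE]
  foot <- foot[valid]

  # amplitude-based artifact rejection: a detected interval whose pulse
  # amplitude is far below the median is a spurious sub-beat (e.g. a
  # dicrotic wave crossing the slope threshold under noise); merge it into
  # its predecessor by deleting its starting foot
  for (iter in seq_along(foot)) {
    n_int <- length(foot) - 1L
    if (n_int < 2) break
    amp <- vapply(seq_len(n_int), function(k)
      max(ps[foot[k]:foot[k + 1L]]) - ps[foot[k]], numeric(1))
    bad <- which(amp < 0.4 * stats::median(amp))
    if (length(bad) == 0) break
    foot <- foot[-bad[1]]
  }

  n_beat <- length(foot) - 1L
  if (n_beat < 1) stop("fewer than 2 beats detected")

  out <- data.frame(
    foot_index = integer(n_beat), peak_index = integer(n_beat),
    notch_index = integer(n_beat), foot_time = numeric(n_beat),
    sbp = numeric(n_beat), dbp = numeric(n_beat), pp = numeric(n_beat),
    systolic_area = numeric(n_beat), map = numeric(n_beat),
    period_s = numeric(n_beat), flagged = logical(n_beat))

  for (k in seq_len(n_beat)) {
    i0 <- foot[k]; i1 <- foot[k + 1L]
    span <- ps[i0:i1]
    pk <- i0 + which.max(span) - 1L
    dbp <- ps[i0]; sbp <- ps[pk]
    notch <- .find_notch(ps, pk, i1, dbp, sbp)
    if (is.na(notch)) {
      sys_end <- min(i1, i0 + round(0.35 * (i1 - i0)))
    } else {
      sys_end <- notch
    }
    idx <- i0:sys_end
    area <- sum(diff(idx) / fs * (pmax(ps[idx] - dbp, 0)[-1] +
                                    pmax(ps[idx] - dbp, 0)[-length(idx)]) / 2)
    period <- (i1 - i0) / fs
    out$foot_index[k] <- i0
    out$peak_index[k] <- pk
    out$notch_index[k] <- ifelse(is.na(notch), NA_integer_, notch)
    out$foot_time[k] <- (i0 - 1) / fs
    out$sbp[k] <- sbp; out$dbp[k] <- dbp; out$pp[k] <- sbp - dbp
    out$systolic_area[k] <- area
    out$map[k] <- mean(ps[i0:(i1 - 1L)])
    out$period_s[k] <- period
    out$flagged[k] <- (60 / period) < 20 || (60 / period) > 250
  }
  out <- out[out$pp > 0 & out$systolic_area > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, sampling_rate = fs, resp_rate = waveform$resp_rate,
            class = c("beat_series", "data.frame"))
}

# First local minimum after the peak that has dropped below half the pulse
# amplitude; NA when no such minimum exists before the next foot.
.find_notch <- function(ps, peak, next_foot, dbp, sbp) {
  if (next_foot - peak < 4) return(NA_integer_)
  half <- dbp + 0.5 * (sbp - dbp)
  i <- (peak + 1L):(next_foot - 1L)
  if (length(i) < 3) return(NA_integer_)
  v <- ps[i]
  n <- length(v)
  j <- 2:(n - 1L)
  cand <- j[v[j] <= v[j - 1L] & v[j] <= v[j + 1L] & v[j] < half]
  if (length(cand) == 0) return(NA_integer_)
  i[cand[1]]
}

#' Estimate stroke volume from systolic area (pulse-contour surrogate)
#'
#' Applies the systolic-area pulse-contour rule `SV = k * systolic_area`.
#' The calibration constant is arbitrary: all downstream variation indices
#' (SVV, dynamic Ea) are invariant to it, so only relative stroke volume
#' matters.
#'
#' @param beats A `beat_series` from [detect_beats()], or a single list/row
#'   with a `systolic_area` element.
#' @param calibration_k Calibration constant, mL per mmHg*s (> 0).
#' @return For a `beat_series`, the same object with an `sv_estimate`
#'   column added; for a single beat, the stroke volume estimate in mL.
#' @export
estimate_stroke_volume <- function(beats, calibration_k = 1) {
  stopifnot(is.numeric(calibration_k), calibration_k > 0)
  area <- beats$systolic_area
  if (is.null(area)) stop("beats must carry a systolic_area")
  if (any(area <= 0)) stop("non-positive systolic_area")
  sv <- calibration_k * area
  if (inherits(beats, "beat_series")) {
    beats$sv_estimate <- sv
    beats
  } else {
    sv
  }
}

#' Segment a beat series into ventilator respiratory cycles
#'
#' Cuts the trace into consecutive clock-aligned windows of one respiratory
#' period (60/`resp_rate` s) starting at time 0, and assigns each beat to
#' the window containing its foot. Windows with fewer than 2 beats are
#' flagged incomplete and excluded from index computation downstream. The
#' windows are clock-aligned because the ventilator rate is set and held
#' fixed; they are not derived from the pressure signal.
#'
#' @param beats A `beat_series` from [detect_beats()].
#' @param resp_rate Respiratory rate, breaths/min; default taken from the
#'   `beat_series` attribute.
#' @return An object of class `resp_windows`: list with `windows` (data
#'   frame `window`, `t_start`, `t_end`, `t_mid`, `n_beats`, `complete`)
#'   and `beat_index` (list of beat row indices per window).
#' @export
segment_respiratory_cycles <- function(beats, resp_rate = attr(beats, "resp_rate")) {
  if (is.null(resp_rate) || !is.finite(resp_rate) || resp_rate <= 0)
    stop("resp_rate must be known (ventilator-set)")
  period <- 60 / resp_rate
  t_max <- if (nrow(beats)) max(beats$foot_time + beats$period_s) else 0
  n_win <- floor(t_max / period)
  if (n_win < 1) {
    return(structure(list(
      windows = data.frame(window = integer(), t_start = numeric(),
                           t_end = numeric(), t_mid = numeric(),
                           n_beats = integer(), complete = logical()),
      beat_index = list()), class = "resp_windows"))
  }
  t_start <- (seq_len(n_win) - 1) * period
  t_end <- t_start + period
  idx <- lapply(seq_len(n_win), function(w)
    which(beats$foot_time >= t_start[w] & beats$foot_time < t_end[w]))
  n_b <- vapply(idx, length, integer(1))
  structure(list(
    windows = data.frame(window = seq_len(n_win), t_start = t_start,
                         t_end = t_end, t_mid = (t_start + t_end) / 2,
                         n_beats = n_b, complete = n_b >= 2),
    beat_index = idx), class = "resp_windows")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats @ %g Hz (resp rate %s/min)\n",
              nrow(x), attr(x, "sampling_rate"),
              format(attr(x, "resp_rate"))))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more beats\n", nrow(x) - 5))
  invisible(x)
}
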