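# Shared fixtures: all built in code, no data files.

# Standard noise-free study-like waveform
sim_wf <- function(heart_rate = 60, resp_rate = 12, duration = 120,
                   m = 0.10, gamma = 1, noise_sd = 0, seed = 1,
                   sampling_rate = 250, ...) {
  simulate_waveform(waveform_sim_config(
    heart_rate = heart_rate, resp_rate = resp_rate, duration = duration,
    sv_modulation_depth = m, tone_exponent = gamma, noise_sd = noise_sd,
    sampling_rate = sampling_rate, seed = seed, ...))
}

# Full waveform -> indices pipeline; returns list(ppv, svv, ea, beats)
wf_indices <- function(wf, calibration_k = 1, at_time = NULL) {
  beats <- estimate_stroke_volume(detect_beats(wf), calibration_k)
  cyc <- segment_respiratory_cycles(beats)
  ppv <- compute_ppv(beats, cyc)
  svv <- compute_svv(beats, cyc)
  at <- at_time %||% max(svv$time_s)
  list(ppv = ppv, svv = svv, beats = beats,
       ea = compute_dynamic_ea(ppv, svv, at))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic beat series built directly from per-beat quantities, bypassing
# waveform rendering: the index-formula test surface.
beat_series_from <- function(pp, sv, period = 1, resp_rate = 12) {
  n <- length(pp)
  structure(data.frame(
    foot_index = seq_len(n), peak_index = seq_len(n), notch_index = NA,
    foot_time = (seq_len(n) - 1) * period,
    sbp = 60 + pp, dbp = 60, pp = pp,
    systolic_area = sv, map = 60 + pp / 3,
    period_s = period, flagged = FALSE, sv_estimate = sv),
    sampling_rate = 100, resp_rate = resp_rate,
    class = c("beat_series", "data.frame"))
}

# Brute-force AUC: exhaustive pairwise comparisons, wins + half ties
auc_brute <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# Brute-force Youden: exhaustive search over distinct thresholds
youden_brute <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  thr <- sort(unique(scores))
  j <- vapply(thr, function(cc) mean(x > cc) + mean(y <= cc) - 1, numeric(1))
  list(cutoff = min(thr[j >= max(j) - 1e-12]), j = max(j))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  pr <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
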