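#' Configuration for the ventilated arterial waveform simulator
#'
#' Bundles the generative parameters of the mechanically ventilated arterial
#' pressure waveform model. Beat-to-beat stroke volume is sinusoidally
#' modulated at the ventilator frequency with relative depth `m`
#' (`sv_modulation_depth`), and pulse pressure is coupled to stroke volume
#' through a power law `PP = k * SV^gamma`. The tone exponent `gamma`
#' (`tone_exponent`) is the simulator's ground-truth analogue of dynamic
#' arterial elastance: in the small-modulation limit the true PPV/SVV ratio
#' equals `gamma`. Likewise `m` sets true SVV at approximately `2 * m * 100`
#' percent (exact value depends on the discrete beat phases sampled within a
#' respiratory cycle).
#'
#' @param heart_rate Heart rate, beats/min. Must exceed `resp_rate`; a
#'   warning is issued below 4 beats per respiratory cycle.
#' @param resp_rate Ventilator respiratory rate, breaths/min (clock-set and
#'   known, as on a ventilated patient).
#' @param sampling_rate Sampling rate of the rendered trace, Hz (>= 25).
#' @param duration Trace duration, s. At least 32 s so that four 8-s PPV
#'   epochs and one 20-s SVV window fit.
#' @param sv_baseline Nominal stroke volume, mL.
#' @param sv_modulation_depth Relative depth `m` of the respiratory stroke
#'   volume modulation, in `[0, 0.5)`.
#' @param tone_exponent Arterial tone exponent `gamma` (> 0) of the
#'   pressure-volume coupling `PP = k * SV^gamma`.
#' @param diastolic_baseline Diastolic pressure floor, mmHg.
#' @param compliance_scale Coupling constant `k`, mmHg per mL^gamma. Default
#'   `NULL` chooses `k` so the nominal pulse pressure is
#'   `pulse_pressure_nominal`.
#' @param pulse_pressure_nominal Nominal pulse pressure at `sv_baseline`,
#'   mmHg; used only when `compliance_scale` is `NULL`.
#' @param baseline_swing Amplitude of an optional additive respiratory swing
#'   of the diastolic baseline, mmHg (default 0: all respiratory modulation
#'   enters through stroke volume).
#' @param noise_sd Additive Gaussian measurement noise, mmHg.
#' @param seed Integer seed; the simulator is bit-reproducible given the seed.
#'
#' @return An object of class `waveform_sim_config` (a validated list).
#' @seealso [simulate_waveform()]
#' @export
waveform_sim_config <- function(heart_rate = 75,
                                resp_rate = 12,
                                sampling_rate = 250,
                                duration = 120,
                                sv_baseline = 80,
                                sv_modulation_depth = 0.10,
                                tone_exponent = 1,
                                diastolic_baseline = 55,
                                compliance_scale = NULL,
                                pulse_pressure_nominal = 45,
                                baseline_swing = 0,
                                noise_sd = 0,
                                seed = 1L) {
  stopifnot(is.numeric(heart_rate), heart_rate > 0,
            is.numeric(resp_rate), resp_rate > 0,
            is.numeric(sampling_rate), is.numeric(duration),
            sv_baseline > 0, diastolic_baseline > 0,
            pulse_pressure_nominal > 0, noise_sd >= 0)
  if (heart_rate <= resp_rate)
    stop("heart_rate must exceed resp_rate (need >= 2 beats per respiratory cycle)")
  if (heart_rate < 4 * resp_rate)
    warning("fewer than 4 beats per respiratory cycle; PPV/SVV extremes are coarsely sampled")
  if (sampling_rate < 25)
    stop("sampling_rate must be >= 25 Hz")
  min_dur <- 32
  if (duration < min_dur)
    stop(sprintf(
      "duration %.1f s too short: need at least %d s (four 8-s PPV epochs and one 20-s SVV window)",
      duration, min_dur))
  if (sv_modulation_depth < 0 || sv_modulation_depth >= 0.5)
    stop("sv_modulation_depth must be in [0, 0.5)")
  if (tone_exponent <= 0)
    stop("tone_exponent must be > 0")
  if (is.null(compliance_scale))
    compliance_scale <- pulse_pressure_nominal / sv_baseline^tone_exponent
  stopifnot(compliance_scale > 0)
  structure(list(
    heart_rate = heart_rate, resp_rate = resp_rate,
    sampling_rate = sampling_rate, duration = duration,
    sv_baseline = sv_baseline, sv_modulation_depth = sv_modulation_depth,
    tone_exponent = tone_exponent, diastolic_baseline = diastolic_baseline,
    compliance_scale = compliance_scale, baseline_swing = baseline_swing,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "waveform_sim_config")
}

# Pulse template constants. The beat is rendered as a smooth systolic lobe
# (sin^2 rise to the peak at 35% of the lobe, raised-cosine fall back to the
# diastolic level) ending in a dicrotic notch at the diastolic baseline, a
# small dicrotic wave, and an exponential diastolic runoff to the next foot.
# The lobe duration scales as (SV/SV0)^(1-gamma) while its amplitude is
# PP = k*SV^gamma, so the systolic area (foot to notch) is exactly
# proportional to SV -- the property the systolic-area pulse-contour
# surrogate relies on.
.pulse <- list(
  sys_frac  = 0.30,  # systolic lobe duration, fraction of the beat period
  peak_frac = 0.35,  # peak position within the lobe
  bump_frac = 0.10,  # dicrotic wave rise time, fraction of the period
  bump_amp  = 0.12,  # dicrotic wave amplitude, fraction of PP; rise kept
                     # gentle so its slope stays well below the systolic
                     # upstroke threshold of beat detectors
  decay_rate = 4     # exponential runoff rate over the diastolic span
)

#' Simulate a mechanically ventilated arterial pressure waveform
#'
#' Renders a stylized radial-artery pressure trace whose beat-to-beat stroke
#' volume is modulated at the ventilator frequency, with analytically known
#' true PPV, SVV and dynamic arterial elastance attached as ground truth.
#'
#' Beat `j` starts at `t_j = j * 60/heart_rate`. Its stroke volume is
#' `SV_j = sv_baseline * (1 + m * sin(2*pi*f_r*t_j))` with `f_r` the
#' respiratory frequency, its pulse pressure `PP_j = k * SV_j^gamma`, and its
#' systolic lobe duration scales as `(SV_j/sv_baseline)^(1-gamma)`, so the
#' area under the systolic lobe is proportional to `SV_j` exactly.
#'
#' Ground truth is evaluated over the first respiratory cycle of the sampled
#' beat sequence: `true_svv = 100*(SV_max - SV_min)/SV_mean`, `true_ppv`
#' computed identically from the `PP_j` sequence, and
#' `true_ea = true_ppv/true_svv` (`NA` when the modulation depth is zero).
#'
#' @param config A [waveform_sim_config()].
#' @return An object of class `waveform_record`: list with `time` (s),
#'   `pressure` (mmHg), `sampling_rate`, `resp_rate`, `heart_rate`,
#'   `ground_truth` (list `true_ppv`, `true_svv`, `true_ea`), `beat_onsets`
#'   (s), `beat_sv` (mL), `beat_pp` (mmHg) and the `config`.
#' @examples
#' wf <- simulate_waveform(waveform_sim_config(heart_rate = 60, resp_rate = 12,
#'                                             duration = 60, seed = 7))
#' wf$ground_truth
#' @export
simulate_waveform <- function(config) {
  stopifnot(inherits(config, "waveform_sim_config"))
  cf <- config
  period <- 60 / cf$heart_rate
  f_r <- cf$resp_rate / 60
  n <- round(cf$duration * cf$sampling_rate)
  t <- (seq_len(n) - 1) / cf$sampling_rate

  n_beats <- floor(cf$duration / period) + 1L
  t_beat <- (seq_len(n_beats) - 1) * period
  sv <- cf$sv_baseline * (1 + cf$sv_modulation_depth * sin(2 * pi * f_r * t_beat))
  pp <- cf$compliance_scale * sv^cf$tone_exponent
  u <- (sv / cf$sv_baseline)^(1 - cf$tone_exponent)

  j <- pmin(floor(t / period) + 1L, n_beats)
  tau <- t - t_beat[j]
  d <- .pulse$sys_frac * period * u[j]          # systolic lobe duration
  wb <- .pulse$bump_frac * period               # dicrotic wave rise time
  h <- .pulse$bump_amp
  rel <- numeric(n)                             # pressure above baseline, / PP_j

  in_sys <- tau <= d
  x <- tau[in_sys] / d[in_sys]
  xp <- .pulse$peak_frac
  rise <- x <= xp
  phi <- numeric(length(x))
  phi[rise] <- sin(0.5 * pi * x[rise] / xp)^2
  phi[!rise] <- 0.5 * (1 + cos(pi * (x[!rise] - xp) / (1 - xp)))
  rel[in_sys] <- phi

  in_bump <- !in_sys & tau <= d + wb
  rel[in_bump] <- h * 0.5 * (1 - cos(pi * (tau[in_bump] - d[in_bump]) / wb))

  in_dia <- !in_sys & !in_bump
  span <- period - d[in_dia] - wb
  y <- (tau[in_dia] - d[in_dia] - wb) / span
  a <- .pulse$decay_rate
  rel[in_dia] <- h * (exp(-a * y) - exp(-a)) / (1 - exp(-a))

  base <- cf$diastolic_baseline + cf$baseline_swing * sin(2 * pi * f_r * t)
  pressure <- base + pp[j] * rel
  set.seed(cf$seed)
  if (cf$noise_sd > 0)
    pressure <- pressure + stats::rnorm(n, 0, cf$noise_sd)

  in_first_cycle <- t_beat >= 0 & t_beat < 60 / cf$resp_rate
  sv1 <- sv[in_first_cycle]
  pp1 <- pp[in_first_cycle]
  true_svv <- 100 * (max(sv1) - min(sv1)) / mean(sv1)
  true_ppv <- 100 * (max(pp1) - min(pp1)) / mean(pp1)
  true_ea <- if (true_svv > 0) true_ppv / true_svv else NA_real_

  structure(list(
    time = t, pressure = pressure,
    sampling_rate = cf$sampling_rate, resp_rate = cf$resp_rate,
    heart_rate = cf$heart_rate,
    ground_truth = list(true_ppv = true_ppv, true_svv = true_svv,
                        true_ea = true_ea),
    beat_onsets = t_beat, beat_sv = sv, beat_pp = pp,
    config = cf
  ), class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf(
    "<waveform_record> %.1f s @ %g Hz, HR %g/min, RR %g/min\n",
    length(x$pressure) / x$sampling_rate, x$sampling_rate,
    x$heart_rate, x$resp_rate))
  gt <- x$ground_truth
  cat(sprintf("  ground truth: PPV %.2f%%  SVV %.2f%%  Ea %s\n",
              gt$true_ppv, gt$true_svv,
              ifelse(is.na(gt$true_ea), "undefined", sprintf("%.3f", gt$true_ea))))
  invisible(x)
}
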