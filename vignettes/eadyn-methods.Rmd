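---
title: "Dynamic arterial elastance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic arterial elastance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eadyn)
```

## Scope

`eadyn` analyses arterial pressure responsiveness to fluid challenge in
mechanically ventilated patients. This vignette documents the models the
package implements, the assumptions behind them, the defaults and why they
were chosen, and what the synthetic-data generators do and do not emulate.

## The indices and their measurement conventions

During positive-pressure ventilation, cyclic changes in intrathoracic
pressure modulate venous return and hence beat-to-beat stroke volume; the
modulation propagates into pulse pressure. Over one respiratory cycle:

* `PPV = 100 · 2(PPmax − PPmin) / (PPmax + PPmin)` — pulse pressure
  variation, in percent, with the extremes taken over the beats of the
  cycle (pulse pressure `PP = SBP − DBP` per beat);
* `SVV = 100 · (SVmax − SVmin) / SVmean` — stroke volume variation, with
  stroke volume from pulse-contour analysis;
* `Ea = PPV / SVV` — dynamic arterial elastance, dimensionless.

The two indices come from different bedside devices with different update
conventions, and the package mirrors this: per-cycle PPV values are
averaged within 8-s epochs and each reported PPV reading is the rolling
mean of 4 consecutive epochs; per-cycle SVV values are averaged within
20-s reporting windows. `compute_dynamic_ea()` takes the mean of the last
3 readings of each series at the requested time and returns the ratio of
averages. We read the measurement convention "averaged over consecutive
cycles of 8 s" as the monitor's rolling 4-epoch average, and we pair the
mismatched 8-s/20-s grids by nearest time; averaging 3 consecutive
readings of each series makes the residual grid offset immaterial, which
is also the argument the bedside protocol itself relies on. Ea is a ratio
of averages, not an average of ratios, because the measurement rule names
the averages of the inputs.

Respiratory cycles are clock-aligned windows of 60/RR seconds from the
start of the trace: on a ventilated patient the rate is set on the
machine and held fixed during measurement, so deriving the cycle from the
pressure signal would add noise for no benefit. Windows holding fewer
than two beats cannot express a within-cycle extreme and are flagged
incomplete and skipped.

## Protocol rules

* **Preload-dependence / hypotension gate** (`check_preload_dependency()`):
  every SVV reading in the trailing 10 minutes strictly greater than 10%,
  and MAP < 65 mmHg or SBP < 90 mmHg. All inequalities strict, as printed
  on protocol sheets.
* **Responder rule** (`classify_responder()`): MAP increase ≥ 15% after
  fluid challenge, boundary inclusive. The comparison applies a 1e-9
  relative guard so that a MAP pair constructed to sit exactly on the
  boundary (e.g. `map2 * 1.15` in double precision) still classifies as a
  responder; no physiologically distinguishable input is affected.

## Beat detection and the stroke-volume surrogate

`detect_beats()` locates systolic upstrokes where the slope of a lightly
smoothed trace (40-ms moving average) exceeds 30% of the 95th percentile
of positive slopes; the diastolic foot is the pressure minimum in the
quarter-beat preceding the upstroke, the systolic peak the maximum before
the next foot. Two artifact rules keep the segmentation honest: intervals
whose pulse amplitude is below 40% of the median are treated as spurious
sub-beats (typically a dicrotic wave crossing the slope threshold under
noise) and merged into their predecessor, and beats whose instantaneous
rate leaves 20–250 beats/min are flagged and excluded from index
computation. Boundary beats are discarded. Traces below 25 Hz or with
less than 1 mmHg of pressure range are rejected with explicit errors.

Commercial pulse-contour algorithms are proprietary, so the package
defines a documented surrogate: systole ends at the dicrotic notch (first
local minimum after the peak that has fallen below half the pulse
amplitude), or at a fixed 0.35 fraction of the instantaneous beat period
when no notch is detectable, and

> `SV = calibration_k × ∫ (p(t) − DBP) dt` over foot → systole end.

The absolute calibration is irrelevant by design: SVV and Ea are ratios,
and the package asserts their invariance to `calibration_k` (and to
rescaling all pressures) at the 1e-12 level. Using systolic area rather
than `SBP − DBP` keeps SVV structurally different from PPV, so Ea is a
non-trivial ratio, as it is with the real two-device setup.

## The waveform simulator and its ground truth

`simulate_waveform()` renders beat `j` at onset `t_j = j·60/HR` with

* stroke volume `SV_j = SV0 · (1 + m · sin(2π f_r t_j))` — sinusoidal
  respiratory modulation of relative depth `m` (true SVV ≈ 200·m %);
* pulse pressure `PP_j = k · SV_j^γ` — a power-law pressure–volume
  coupling. The tone exponent γ is the minimal one-parameter model of
  arterial vascular tone, and it makes the true Ea equal γ in the
  small-modulation limit, giving the pipeline a clean recovery target;
* a pulse template with a smooth systolic lobe (sin² rise to the peak at
  35% of the lobe, raised-cosine fall) ending in a dicrotic notch at the
  diastolic baseline, followed by a small dicrotic wave (12% of PP, slow
  rise) and an exponential diastolic runoff to the next foot.

The systolic lobe's amplitude is `PP_j` while its *duration* scales as
`(SV_j/SV0)^(1−γ)`, so the area under the lobe is exactly proportional to
`SV_j`. This is the key design decision: a template with a fixed shape
would make systolic area proportional to pulse pressure, the SV surrogate
would then recover PP variation, and estimated Ea would equal 1 for every
γ — the generator would be incapable of producing a non-trivial tone
signal. Physiologically the scaling captures the fact that at high tone
(γ > 1) a larger stroke volume is ejected into a stiffer system over a
relatively shorter systole. The dicrotic wave is kept low and slow so its
upstroke stays well below the beat detector's slope threshold even with
noise.

Ground truth is evaluated on the first respiratory cycle of the beat
sequence: `true_svv = 100·(SVmax − SVmin)/SVmean`, `true_ppv` by the same
range/mean formula applied to the `PP_j` sequence (the two PPV
denominators — midrange and mean — agree to first order in `m` and
exactly for phase-symmetric beat sets), and `true_ea` their ratio.
Additive Gaussian measurement noise and an optional respiratory baseline
swing (default 0) complete the model. Everything is deterministic given
the seed.

What the simulator does **not** emulate: intrathoracic-pressure offsets
acting directly on the pressure waveform, heart-rate variability,
arrhythmia, reflected waves, damping/resonance of the catheter-transducer
system, and drifts of tone within a recording. Passing the recovery tests
therefore shows that the index pipeline is correct and unbiased on a
clean, stationary signal with known coupling — not that it is robust to
every clinical artifact.

Defaults: HR 75/min, RR 12/min (ratio > 4 beats per cycle, warning
below), 250 Hz sampling (landmark quantization at 100 Hz is already
acceptable, 250 Hz makes discretization negligible), SV0 80 mL, nominal
PP 45 mmHg over a 55 mmHg diastolic baseline (a hypotensive, vasodilated
patient), `m = 0.10` (SVV ≈ 19%, a clearly preload-dependent state),
γ = 1, noise 0. The minimum duration is 32 s — four 8-s PPV epochs, which
also covers a 20-s SVV window; Ea at a time point additionally needs
three 20-s SVV readings, i.e. at least ~80 s of trace.

## The cohort simulator

`simulate_cohort()` draws each patient's pre-challenge Ea from one of two
Normal components (defaults 0.79 and 0.61, the reported group means in
preload-dependent hypotensive patients; 17 of 39 patients from the
responder-like component) and generates the MAP response as

> `ΔMAP% = β0 + β1·Ea + ε`, `ε ~ N(0, noise_sd)`,

with T3 MAP equal to `T2 MAP · (1 + ΔMAP%/100)`. Responder labels are
never stored: they are recomputed downstream from the T2/T3 MAP values,
so the generator→classifier round trip is itself a test surface (with
`noise_sd = 0` the labels are exactly `Ea ≥ 0.75`).

Calibration, chosen once: `β0 = −30, β1 = 60` place the +15% boundary at
Ea = 0.75, between the component means; `ea_sd = 0.145` makes the
binormal component AUC `Φ(0.18/(0.145·√2)) ≈ 0.81`; `noise_sd = 12`
makes the *induced* AUC of Ea against the MAP-derived labels (obtained by
numerically integrating the Ea mixture against the Gaussian response
noise) also ≈ 0.81, the discrimination reported for this index. T2 states
are drawn inside the gate by construction (MAP 55–64 mmHg, SVV 11–16%).
Because no patient-level distributions were ever published, these SDs are
free parameters of the emulation: the synthetic cohort reproduces the
*structure* of the analysis, not any specific patient table.

For confidence-interval calibration studies the package provides
`simulate_binormal_scores()`, which draws scores with the label equal to
the mixture component so the true AUC is the closed form
`Φ((μ1−μ0)/√(σ1²+σ0²))`; the MAP-threshold labels of the full cohort
generator would make that closed form wrong.

## Cohort statistics

* `compare_groups()` applies the perioperative-literature selection rule:
  Shapiro–Wilk per group; Student t (equal variances) only when both
  groups pass at α = 0.05, otherwise Mann–Whitney; chi-square for
  categorical variables unless any expected cell count is ≤ 5, then
  Fisher's exact test. The boundary is ≤ 5 (not < 5) so that the classic
  fully-separated 10/0–0/10 table, whose expected counts are all exactly
  5, belongs to the exact test.
* `rm_anova_two_way()` is the classical mixed design (subjects nested in
  group, repeated time factor), fitted via `aov` with an
  `Error(subject)` stratum; no sphericity correction is applied, matching
  the SigmaPlot-style analysis it emulates. Degenerate strata are handled
  explicitly (all-equal data give F = 0, p = 1; a pure group offset with
  zero residual gives F = ∞, p = 0). Missing cells are an error, never
  imputed.
* `roc_analysis()` computes the empirical ROC with the orientation fixed
  (higher score ⇒ predicted responder; rule `score > cutoff`) and
  auto-flip disabled — a sign error should surface as AUC < 0.5, not be
  hidden. The AUC is computed from mid-ranks and is therefore *exactly*
  the normalized Mann–Whitney U with ties counted ½. The variance is
  DeLong's placement-value estimator; the default interval is a Wald
  interval on the logit scale, back-transformed. The plain Wald interval
  (`ci_method = "wald"`) covers the true AUC slightly below nominal at
  n ≈ 39 and AUC ≈ 0.8, while the logit-scale interval is close to
  nominal there; both are exposed, and the logit form is the default for
  exactly that reason. The Youden cut-off maximizes
  sensitivity + specificity − 1 over the observed thresholds, ties broken
  toward the lowest cut-off (favouring sensitivity); the exported cut-off
  table enumerates every distinct score with sensitivity and specificity
  in percent. No multiplicity correction is applied across variables:
  each AUC is reported individually.
* `sample_size_auc()` implements the Hanley–McNeil method with
  `Q1 = θ/(2−θ)`, `Q2 = 2θ²/(1+θ)`. The default variance is the
  large-sample form `v(θ) = (Q1−θ²)/κ + (Q2−θ²)` per positive (κ
  negatives per positive), giving for AUC 0.75 vs 0.5, two-sided
  α = 0.05, power 0.80 and equal allocation `n = ⌈18.98⌉ = 19` per group,
  38 in total, and 42 enrolled at 10% dropout (nearest-integer rounding;
  a ceiling-of-`n/(1−d)` rule would give 43 and is rejected). The
  finite-sample variance with its `(n−1)` weights is available as
  `variance = "small_sample"`; it is slightly more conservative (40 at
  the default design) and is deliberately *not* the default, because the
  large-sample form is the variant consistent with the published designs
  this routine reproduces. Two-sided α and 1:1 allocation are likewise
  the documented defaults.

## Numerical choices

* Landmark detection runs on a 40-ms moving average; peak flattening from
  the smoothing is below 2% of PP, proportional across beats, and cancels
  in all variation ratios.
* Systolic-area integration is trapezoidal on the sampled grid; both
  integration boundaries sit where the integrand vanishes (foot, notch at
  diastolic level), so one-sample boundary jitter contributes only
  second-order area error.
* With exact per-beat quantities the index machinery reproduces Ea = 1
  for proportional coupling to machine precision; the full
  render→detect→integrate route carries ~2×10⁻⁴ discretization error at
  250 Hz, far inside the ±0.05 recovery tolerance asserted end-to-end.
* Ties in the Youden search are broken toward the lowest threshold;
  AUC/U-statistic ties count ½ everywhere.

## Problem sizes

The test suite simulates 60–120 s traces at 250 Hz, cohorts of 39
patients, 400–1000 replicate cohorts for the Monte-Carlo calibration
checks, 200 random instances for the exhaustive ROC oracles, and all 2×2
tables with margins ≤ 12 for the Fisher enumeration — sizes chosen so the
whole suite runs in about a minute on a laptop while keeping Monte-Carlo
error well below the asserted tolerances.

## Known limitations

* The stroke-volume surrogate is linear in systolic area with a free
  calibration; absolute stroke volumes (and thus cardiac output) are out
  of scope — only variation indices are meaningful.
* Respiratory windows are clock-aligned from trace start; a trace whose
  recording started mid-breath will have its cycle boundaries offset from
  the physiologic breath, which leaves within-cycle extremes intact but
  can split one breath across two windows.
* The beat detector targets regular rhythms; arrhythmia handling is
  limited to flagging out-of-range RR intervals (studies of these indices
  exclude arrhythmia).
* Device file formats are out of scope: waveforms and cohorts travel as
  plain CSV with a JSON metadata sidecar.
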