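test_that("PPV and SVV formulas give the textbook values on known beats", {
  # one respiratory cycle of 5 beats, PP alternating 40..50
  pp <- c(50, 45, 40, 45, 50)
  sv <- c(100, 90, 80, 90, 100)
  beats <- beat_series_from(rep(pp, 8), rep(sv, 8), period = 1, resp_rate = 12)
  cyc <- segment_respiratory_cycles(beats)
  ppv <- compute_ppv(beats, cyc)
  svv <- compute_svv(beats, cyc)
  expect_equal(unique(round(ppv$ppv, 10)), 100 * 2 * 10 / 90)  # 22.22%
  expect_equal(unique(round(svv$svv, 10)), 100 * 20 / 92)      # SVmean = 92
  # constant PP and SV: both zero
  beats0 <- beat_series_from(rep(50, 40), rep(90, 40))
  cyc0 <- segment_respiratory_cycles(beats0)
  expect_equal(unique(compute_ppv(beats0, cyc0)$ppv), 0)
  expect_equal(unique(compute_svv(beats0, cyc0)$svv), 0)
})

test_that("index recovery from rendered waveforms matches generator truth", {
  for (m in c(0.05, 0.10, 0.15)) {
    wf <- sim_wf(heart_rate = 60, resp_rate = 12, duration = 120, m = m,
                 gamma = 1, seed = 2)
    idx <- wf_indices(wf)
    expect_lt(abs(mean(idx$svv$svv) - wf$ground_truth$true_svv),
              0.10 * wf$ground_truth$true_svv)
    expect_lt(abs(mean(idx$ppv$ppv) - wf$ground_truth$true_ppv),
              0.10 * wf$ground_truth$true_ppv)
  }
})

test_that("dynamic Ea recovers the arterial tone exponent", {
  # exact-beat route: with PP = k*SV^1 the ratio is 1 to machine precision
  sv <- 80 * (1 + 0.1 * sin(2 * pi * 0.2 * (0:64)))
  beats <- beat_series_from(0.5 * sv, sv, period = 1, resp_rate = 12)
  cyc <- segment_respiratory_cycles(beats)
  ea <- compute_dynamic_ea(compute_ppv(beats, cyc), compute_svv(beats, cyc), 60)
  expect_lt(abs(ea - 1), 1e-6)

  # full waveform route: Ea within 0.05 of gamma
  for (g in c(0.6, 0.8, 1.0, 1.2)) {
    wf <- sim_wf(heart_rate = 60, resp_rate = 12, duration = 120, m = 0.12,
                 gamma = g, seed = 4)
    expect_lt(abs(wf_indices(wf)$ea - g), 0.05)
  }
})

test_that("Ea uses the mean of the last three paired readings", {
  ppv <- data.frame(time_s = c(10, 20, 30, 40), ppv = c(30, 22, 22, 22))
  svv <- data.frame(time_s = c(20, 40, 60), svv = c(20, 20, 20))
  # only readings at or before t: PPV (30,22,22), SVV needs 3 -> t=60
  expect_error(compute_dynamic_ea(ppv, svv, 40), "need 3 readings")
  expect_equal(compute_dynamic_ea(ppv, svv, 60), mean(c(22, 22, 22)) / 20)
  svv0 <- data.frame(time_s = c(20, 40, 60), svv = c(0, 0, 0))
  expect_error(compute_dynamic_ea(ppv, svv0, 60), "SVV zero")
  # identical series: Ea exactly 1
  s <- data.frame(time_s = c(20, 40, 60), svv = c(12, 13, 14))
  p <- data.frame(time_s = c(20, 40, 60), ppv = c(12, 13, 14))
  expect_equal(compute_dynamic_ea(p, s, 60), 1.0)
})

test_that("indices are invariant to pressure and calibration rescaling", {
  wf <- sim_wf(duration = 80, m = 0.12, gamma = 0.8, seed = 6)
  beats <- detect_beats(wf)
  cyc <- segment_respiratory_cycles(estimate_stroke_volume(beats, 1))

  b_a <- estimate_stroke_volume(beats, 1)
  b_b <- estimate_stroke_volume(beats, 7.3)     # calibration rescale
  expect_equal(compute_svv(b_a, cyc)$svv, compute_svv(b_b, cyc)$svv,
               tolerance = 1e-13)

  wf2 <- wf
  wf2$pressure <- wf$pressure * 3               # pressure rescale
  beats2 <- estimate_stroke_volume(detect_beats(wf2), 1)
  cyc2 <- segment_respiratory_cycles(beats2)
  p1 <- compute_ppv(b_a, cyc); p2 <- compute_ppv(beats2, cyc2)
  s1 <- compute_svv(b_a, cyc); s2 <- compute_svv(beats2, cyc2)
  expect_equal(p2$ppv, p1$ppv, tolerance = 1e-12)
  expect_equal(s2$svv, s1$svv, tolerance = 1e-12)
  expect_equal(compute_dynamic_ea(p2, s2, 60), compute_dynamic_ea(p1, s1, 60),
               tolerance = 1e-12)
})

test_that("estimated Ea increases with the tone exponent", {
  eas <- vapply(c(0.6, 0.8, 1.0, 1.2, 1.4), function(g)
    wf_indices(sim_wf(duration = 120, m = 0.10, gamma = g, seed = 5))$ea,
    numeric(1))
  expect_true(all(diff(eas) > 0))
})

test_that("responder rule is boundary-inclusive at +15%", {
  expect_true(classify_responder(60, 69))    # exactly +15.0%
  expect_false(classify_responder(60, 68))   # +13.3%
  expect_true(classify_responder(60, 70))    # +16.7%
  expect_error(classify_responder(0, 69), "positive")
})

test_that("preload-dependence gate applies strict thresholds", {
  svv_ok <- data.frame(time_s = seq(0, 660, by = 20), svv = 12)
  expect_true(check_preload_dependency(svv_ok, map = 60, sbp = 95))
  expect_false(check_preload_dependency(svv_ok, map = 70, sbp = 95))   # no hypotension
  expect_true(check_preload_dependency(svv_ok, map = 70, sbp = 85))    # SBP arm
  svv_dip <- svv_ok
  svv_dip$svv[20] <- 10.0                       # touches threshold: strict >
  expect_false(check_preload_dependency(svv_dip, map = 60, sbp = 95))
  short <- data.frame(time_s = seq(0, 300, by = 20), svv = 12)
  expect_error(check_preload_dependency(short, 60, 95), "insufficient history")
})
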