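test_that("cohort has the requested size and always satisfies the T2 gate", {
  coh <- simulate_cohort(cohort_sim_config(n_patients = 39, seed = 7))
  expect_equal(length(unique(coh$patient_id)), 39L)
  expect_equal(nrow(coh), 39L * 4L)
  t2 <- coh[coh$timepoint == "T2", ]
  expect_true(all(t2$svv > 10))
  expect_true(all(t2$map < 65 | t2$sbp < 90))
  expect_true(all(coh$map < coh$sbp))
  expect_true(all(coh$map > 0))
})

test_that("MAP response model is exact linear arithmetic without noise", {
  # beta0 = -30, beta1 = 60: a patient with Ea = 0.75 sits exactly on +15%
  cfg <- cohort_sim_config(noise_sd = 0, ea_sd = 0, seed = 1,
                           ea_mean_responder = 0.75,
                           ea_mean_nonresponder = 0.75)
  coh <- simulate_cohort(cfg)
  r <- cohort_responders(coh)
  expect_equal(r$delta_map_pct, rep(15, 39), tolerance = 1e-9)
  expect_true(all(r$responder))   # boundary inclusive
})

test_that("responder labels round-trip through the MAP values when noiseless", {
  cfg <- cohort_sim_config(noise_sd = 0, seed = 3)
  coh <- simulate_cohort(cfg)
  r <- cohort_responders(coh)
  # with dMAP = -30 + 60*Ea the responder rule is exactly Ea >= 0.75
  expect_identical(r$responder, unname(attr(coh, "ea_true") >= 0.75))
  expect_identical(r$responder,
                   classify_responder(r$map_before, r$map_after))
})

test_that("cohort generation is deterministic in the seed", {
  a <- simulate_cohort(cohort_sim_config(seed = 5))
  b <- simulate_cohort(cohort_sim_config(seed = 5))
  c <- simulate_cohort(cohort_sim_config(seed = 6))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("configuration errors are raised for invalid designs", {
  expect_error(cohort_sim_config(n_patients = 0), "positive count")
  expect_error(cohort_sim_config(t2_map_range = c(60, 70)), "below the 65")
  expect_error(cohort_sim_config(svv_range = c(8, 12)), "strictly above the 10")
  expect_error(
    simulate_cohort(cohort_sim_config(beta0 = -300, noise_sd = 0, seed = 1)),
    "non-positive T3 MAP")
})

test_that("empirical cohort AUC matches numerical integration of the model", {
  # truth for labels I(beta0 + beta1*Ea + eps >= 15): integrate the Ea
  # mixture against the Gaussian response noise on a grid
  cfg <- cohort_sim_config(seed = 1)
  p_r <- cfg$n_responders / cfg$n_patients
  g <- function(e) p_r * dnorm(e, cfg$ea_mean_responder, cfg$ea_sd) +
    (1 - p_r) * dnorm(e, cfg$ea_mean_nonresponder, cfg$ea_sd)
  w <- function(e) pnorm((cfg$beta0 + cfg$beta1 * e - 15) / cfg$noise_sd)
  e <- seq(0, 1.8, length.out = 4001); de <- diff(e)[1]
  ge <- g(e); we <- w(e)
  f1 <- ge * we; f1 <- f1 / (sum(f1) * de)
  f0 <- ge * (1 - we); f0 <- f0 / (sum(f0) * de)
  F0 <- cumsum(f0) * de
  auc_true <- sum(f1 * (F0 - 0.5 * f0 * de)) * de

  set.seed(20)
  aucs <- replicate(400, {
    coh <- simulate_cohort(cohort_sim_config(seed = sample.int(2^31 - 1, 1)))
    r <- cohort_responders(coh)
    if (sum(r$responder) < 2 || sum(!r$responder) < 2) return(NA_real_)
    t2 <- coh[coh$timepoint == "T2", ]
    roc_analysis(t2$ea[match(r$patient_id, t2$patient_id)], r$responder)$auc
  })
  aucs <- aucs[!is.na(aucs)]
  mc_se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - auc_true), 4 * mc_se + 0.005)
  expect_equal(auc_true, 0.81, tolerance = 0.01)  # calibration of the defaults
})

test_that("binormal score generator matches its closed-form AUC", {
  expect_equal(binormal_auc(0.79, 0.61, 0.145), pnorm(0.18 / (0.145 * sqrt(2))))
  set.seed(14)
  aucs <- replicate(600, {
    s <- simulate_binormal_scores(17, 22)
    roc_analysis(s$scores, s$labels)$auc
  })
  truth <- binormal_auc(0.79, 0.61, 0.145)
  expect_lt(abs(mean(aucs) - truth), 4 * sd(aucs) / sqrt(600) + 0.005)
})
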