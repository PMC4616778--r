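#' Configuration for the hemodynamic cohort simulator
#'
#' Defines a synthetic two-group cohort in which dynamic arterial elastance
#' (Ea) stochastically determines the mean arterial pressure response to a
#' fluid challenge. Each patient's Ea at the pre-challenge time point (T2)
#' is drawn from one of two Normal components whose means default to the
#' group means reported in preload-dependent hypotensive patients (0.79 for
#' the responder-like component, 0.61 for the nonresponder-like one). The
#' MAP response is linear in Ea with Gaussian noise,
#' `dMAP% = beta0 + beta1 * Ea + eps`, and responder labels are *never*
#' drawn directly: they are recomputed downstream from the T2/T3 MAP values
#' with the >= 15% rule, so the generator-to-classifier round trip is a
#' test surface.
#'
#' Default calibration, chosen once: `ea_sd = 0.145` makes the binormal
#' component separation `pnorm(0.18 / (0.145 * sqrt(2))) ~ 0.81`, the
#' discrimination reported for Ea; `beta0 = -30`, `beta1 = 60` place the
#' +15% response boundary exactly at Ea = 0.75, between the two component
#' means; and `noise_sd = 12` makes the *induced* AUC of Ea against the
#' downstream-derived labels (computable by numerical integration of the
#' mixture against the Gaussian response noise) also approximately 0.81.
#'
#' @param n_patients Number of patients (default 39).
#' @param n_responders Number of patients drawn from the responder-like Ea
#'   component; default `round(n_patients * 17/39)` (the 17/22 split).
#' @param ea_mean_responder,ea_mean_nonresponder Component means of T2 Ea.
#' @param ea_sd Common component SD of T2 Ea.
#' @param beta0,beta1 Intercept (%) and slope (% per Ea unit) of the MAP
#'   response model.
#' @param noise_sd SD of the Gaussian noise on `dMAP%` (percentage points).
#' @param t2_map_range T2 MAP interval, mmHg, below the 65 mmHg hypotension
#'   threshold (default `c(55, 64)`).
#' @param svv_range T2 SVV interval, percent, above the 10% preload gate
#'   (default `c(11, 16)`).
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_config`.
#' @seealso [simulate_cohort()], [cohort_responders()]
#' @export
cohort_sim_config <- function(n_patients = 39,
                              n_responders = NULL,
                              ea_mean_responder = 0.79,
                              ea_mean_nonresponder = 0.61,
                              ea_sd = 0.145,
                              beta0 = -30,
                              beta1 = 60,
                              noise_sd = 12,
                              t2_map_range = c(55, 64),
                              svv_range = c(11, 16),
                              seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be a positive count")
  n_patients <- as.integer(n_patients)
  if (is.null(n_responders)) n_responders <- round(n_patients * 17 / 39)
  n_responders <- as.integer(n_responders)
  stopifnot(n_responders >= 0, n_responders <= n_patients,
            ea_sd >= 0, noise_sd >= 0,
            length(t2_map_range) == 2, t2_map_range[1] <= t2_map_range[2],
            length(svv_range) == 2, svv_range[1] <= svv_range[2])
  if (t2_map_range[2] >= 65)
    stop("t2_map_range must lie below the 65 mmHg hypotension threshold")
  if (svv_range[1] <= 10)
    stop("svv_range must lie strictly above the 10% preload-dependence gate")
  structure(list(
    n_patients = n_patients, n_responders = n_responders,
    ea_mean_responder = ea_mean_responder,
    ea_mean_nonresponder = ea_mean_nonresponder, ea_sd = ea_sd,
    beta0 = beta0, beta1 = beta1, noise_sd = noise_sd,
    t2_map_range = t2_map_range, svv_range = svv_range,
    seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

#' Simulate a hemodynamic cohort with known ground truth
#'
#' Generates per-patient snapshots at the four protocol time points:
#' T1 (post-positioning baseline), T2 (just before fluid challenge, always
#' satisfying the preload-dependence and hypotension gate by construction),
#' T3 (3 min after the 500-mL fluid challenge) and T4 (skin closure). T3
#' MAP is `T2 MAP * (1 + dMAP%/100)` with
#' `dMAP% = beta0 + beta1 * Ea + eps`, `eps ~ N(0, noise_sd)`. Responder
#' labels are not stored; recompute them with [cohort_responders()].
#'
#' @param config A [cohort_sim_config()].
#' @return A long-format data frame, one row per patient per time point:
#'   `patient_id`, `timepoint` (`T1`-`T4`), `map`, `sbp`, `hr`,
#'   `cardiac_index`, `stroke_volume_index`, `svv`, `ppv`, `ea`. Attributes
#'   `config`, `ea_true` (the drawn T2 Ea per patient) and
#'   `delta_map_pct` (the realized MAP response) carry the ground truth.
#' @examples
#' coh <- simulate_cohort(cohort_sim_config(seed = 11))
#' table(cohort_responders(coh)$responder)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cf <- config
  n <- cf$n_patients
  set.seed(cf$seed)

  component <- sample(rep(c(TRUE, FALSE),
                          c(cf$n_responders, n - cf$n_responders)))
  mu <- ifelse(component, cf$ea_mean_responder, cf$ea_mean_nonresponder)
  ea <- pmax(stats::rnorm(n, mu, cf$ea_sd), 0.05)

  map2 <- stats::runif(n, cf$t2_map_range[1], cf$t2_map_range[2])
  svv2 <- stats::runif(n, cf$svv_range[1], cf$svv_range[2])
  dmap <- cf$beta0 + cf$beta1 * ea + stats::rnorm(n, 0, cf$noise_sd)
  map3 <- map2 * (1 + dmap / 100)
  if (any(map3 <= 0))
    stop("map_model produced a non-positive T3 MAP; check beta0/beta1/noise_sd")

  hr2 <- stats::runif(n, 60, 90)
  ci2 <- stats::runif(n, 2.0, 3.2)

  snap <- function(tp, map, svv, hr, ci) {
    data.frame(patient_id = sprintf("P%02d", seq_len(n)), timepoint = tp,
               map = map, sbp = map * 1.5, hr = hr, cardiac_index = ci,
               stroke_volume_index = 1000 * ci / hr,
               svv = svv, ppv = ea * svv, ea = ea)
  }
  t1 <- snap("T1", stats::runif(n, 68, 85), stats::runif(n, 8, 14),
             hr2 + stats::runif(n, -5, 5), ci2 * stats::runif(n, 1.0, 1.15))
  t2 <- snap("T2", map2, svv2, hr2, ci2)
  t3 <- snap("T3", map3, pmax(svv2 - stats::runif(n, 2, 6), 2),
             hr2 - stats::runif(n, 0, 8), ci2 * (1 + pmax(dmap, 0) / 150))
  t4 <- snap("T4", stats::runif(n, 70, 90), stats::runif(n, 4, 10),
             hr2 - stats::runif(n, 0, 10), ci2 * stats::runif(n, 0.95, 1.2))
  out <- rbind(t1, t2, t3, t4)
  out <- out[order(out$patient_id, out$timepoint), ]
  rownames(out) <- NULL

  stopifnot(all(t2$svv > 10), all(t2$map < 65 | t2$sbp < 90))
  structure(out, config = cf, ea_true = ea, delta_map_pct = dmap,
            class = c("cohort_frame", "data.frame"))
}

#' Recompute responder labels from a cohort's MAP values
#'
#' Applies the >= 15% MAP-increase rule ([classify_responder()]) to the T2
#' and T3 snapshots of each patient. This is the only way labels enter the
#' analysis: the simulator never stores them.
#'
#' @param cohort A long-format cohort data frame (from [simulate_cohort()]
#'   or [read_cohort_csv()]).
#' @param before,after Time points used as before/after the fluid challenge
#'   (defaults `"T2"`, `"T3"`).
#' @return Data frame `patient_id`, `map_before`, `map_after`,
#'   `delta_map_pct`, `responder`.
#' @export
cohort_responders <- function(cohort, before = "T2", after = "T3") {
  b <- cohort[cohort$timepoint == before, c("patient_id", "map")]
  a <- cohort[cohort$timepoint == after, c("patient_id", "map")]
  m <- merge(b, a, by = "patient_id", suffixes = c("_before", "_after"))
  if (nrow(m) == 0) stop(sprintf("no patients with both %s and %s snapshots", before, after))
  m <- m[order(m$patient_id), ]
  data.frame(patient_id = m$patient_id,
             map_before = m$map_before, map_after = m$map_after,
             delta_map_pct = 100 * (m$map_after - m$map_before) / m$map_before,
             responder = classify_responder(m$map_before, m$map_after),
             row.names = NULL)
}

#' Binormal score generator and its closed-form AUC
#'
#' Draws diagnostic scores from two Normal components with the class label
#' equal to the component — the score-level design used for confidence
#' interval calibration studies, where the true AUC must be known exactly:
#' for components `N(mu_pos, sd_pos)` and `N(mu_neg, sd_neg)` the true AUC
#' is `pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`.
#'
#' @param n_pos,n_neg Number of positive (responder) and negative draws.
#' @param mu_pos,mu_neg Component means (defaults 0.79 and 0.61).
#' @param sd_pos,sd_neg Component SDs (default 0.145).
#' @param seed Optional integer seed.
#' @return List with `scores`, `labels` (logical) and `true_auc`.
#' @export
simulate_binormal_scores <- function(n_pos = 17, n_neg = 22,
                                     mu_pos = 0.79, mu_neg = 0.61,
                                     sd_pos = 0.145, sd_neg = sd_pos,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scores <- c(stats::rnorm(n_pos, mu_pos, sd_pos),
              stats::rnorm(n_neg, mu_neg, sd_neg))
  list(scores = scores,
       labels = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
       true_auc = binormal_auc(mu_pos, mu_neg, sd_pos, sd_neg))
}

#' @rdname simulate_binormal_scores
#' @export
binormal_auc <- function(mu_pos, mu_neg, sd_pos, sd_neg = sd_pos) {
  stats::pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}
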