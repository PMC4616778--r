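#' Normality-gated two-group comparison
#'
#' Compares one variable between two patient groups with the test-selection
#' rule used throughout perioperative studies: continuous variables are
#' tested per group for normality (Shapiro-Wilk); when both groups have
#' Shapiro-Wilk p >= 0.05 an unpaired Student t test (equal variances) is
#' used, otherwise the Mann-Whitney rank-sum test. Categorical variables go
#' to the chi-square test unless any expected cell count is 5 or fewer,
#' in which case Fisher's exact test is used. All p-values are two-sided.
#'
#' @param values Numeric vector (continuous) or factor/character
#'   (categorical), one entry per patient.
#' @param labels Binary group labels (logical, 0/1 or two-level factor).
#' @param variable_kind `"continuous"` or `"categorical"`.
#' @param variable Optional variable name carried into the result.
#' @param normality_alpha Shapiro-Wilk significance level gating the t test
#'   (default 0.05).
#' @return An object of class `group_comparison`: list with `variable`,
#'   `test_used` (`"t_test"`, `"mann_whitney"`, `"chi_square"` or
#'   `"fisher_exact"`), `statistic`, `p_value`, `normality_p` (continuous
#'   only) and per-group `summary`.
#' @export
compare_groups <- function(values, labels,
                           variable_kind = c("continuous", "categorical"),
                           variable = NULL,
                           normality_alpha = 0.05) {
  variable_kind <- match.arg(variable_kind)
  labels <- .as_binary(labels)
  stopifnot(length(values) == length(labels))
  if (sum(labels) == 0 || sum(!labels) == 0) stop("one group is empty")

  if (variable_kind == "continuous") {
    g1 <- values[labels]; g0 <- values[!labels]
    if (length(g1) < 3 || length(g0) < 3)
      stop("need at least 3 patients per group for a continuous comparison")
    sw <- function(v) tryCatch(stats::shapiro.test(v)$p.value,
                               error = function(e) NA_real_)
    norm_p <- c(group1 = sw(g1), group0 = sw(g0))
    normal <- all(!is.na(norm_p)) && all(norm_p >= normality_alpha)
    if (normal) {
      ht <- stats::t.test(g1, g0, var.equal = TRUE)
      test_used <- "t_test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(g1, g0))
      test_used <- "mann_whitney"
    }
    summary <- data.frame(
      group = c("group1", "group0"), n = c(length(g1), length(g0)),
      mean = c(mean(g1), mean(g0)), sd = c(stats::sd(g1), stats::sd(g0)),
      median = c(stats::median(g1), stats::median(g0)))
    res <- list(variable = variable, test_used = test_used,
                statistic = unname(ht$statistic), p_value = ht$p.value,
                normality_p = norm_p, summary = summary)
  } else {
    tab <- table(factor(values), factor(labels, levels = c(FALSE, TRUE)))
    if (any(dim(tab) < 2)) stop("categorical comparison needs >= 2 levels and both groups")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected <= 5)) {
      ht <- stats::fisher.test(tab)
      test_used <- "fisher_exact"
      statistic <- NA_real_
    } else {
      ht <- stats::chisq.test(tab)
      test_used <- "chi_square"
      statistic <- unname(ht$statistic)
    }
    res <- list(variable = variable, test_used = test_used,
                statistic = statistic, p_value = ht$p.value,
                normality_p = NULL, summary = as.data.frame.matrix(tab))
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s %s: p = %.4g\n",
              if (is.null(x$variable)) "" else paste0(" ", x$variable),
              x$test_used, x$p_value))
  invisible(x)
}

#' Two-way repeated-measures ANOVA (group x time)
#'
#' Classical sums-of-squares decomposition for a design with one
#' between-subject factor (group) and one within-subject factor (time),
#' subjects nested in group — the model used to compare the evolution of
#' hemodynamic variables across the protocol time points between responders
#' and nonresponders. Fitting is done with [stats::aov()] and an
#' `Error(subject)` stratum; no sphericity correction is applied. The
#' design must be complete: a missing time point for any patient is an
#' error, never imputed.
#'
#' @param data Data frame in long format.
#' @param value,subject,group,time Names of the columns holding the
#'   response, subject id, group and time point.
#' @return Data frame with one row per effect (`group`, `time`,
#'   `group:time`): `df`, `df_error`, `F`, `p`. Degenerate strata (zero
#'   residual variance) give `F = 0, p = 1` for null effects and
#'   `F = Inf, p = 0` for non-null ones.
#' @export
rm_anova_two_way <- function(data, value = "value", subject = "subject",
                             group = "group", time = "time") {
  d <- data.frame(value = data[[value]],
                  subject = factor(data[[subject]]),
                  group = factor(data[[group]]),
                  time = factor(data[[time]]))
  if (any(is.na(d$value))) stop("missing response values; no imputation is performed")
  tab <- table(d$subject, d$time)
  if (any(tab != 1))
    stop("unbalanced design: every subject needs exactly one value per time point")
  subj_group <- unique(d[, c("subject", "group")])
  if (anyDuplicated(subj_group$subject))
    stop("each subject must belong to exactly one group")
  if (min(table(subj_group$group)) < 2) stop("need >= 2 subjects per group")

  fit <- stats::aov(value ~ group * time + Error(subject), data = d)
  s_between <- summary(fit)[["Error: subject"]][[1]]
  s_within <- summary(fit)[["Error: Within"]][[1]]
  eff <- function(stratum, name) {
    rn <- trimws(rownames(stratum))
    i <- match(name, rn)
    r <- match("Residuals", rn)
    ss <- stratum[i, "Sum Sq"]; df <- stratum[i, "Df"]
    ss_e <- stratum[r, "Sum Sq"]; df_e <- stratum[r, "Df"]
    ms <- ss / df; ms_e <- ss_e / df_e
    if (!is.finite(ms_e) || ms_e < 1e-12) {
      if (ss < 1e-12) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
    } else {
      f <- ms / ms_e
      p <- stats::pf(f, df, df_e, lower.tail = FALSE)
    }
    data.frame(effect = name, df = df, df_error = df_e, F = f, p = p)
  }
  out <- rbind(eff(s_between, "group"),
               eff(s_within, "time"),
               eff(s_within, "group:time"))
  rownames(out) <- NULL
  out
}

#' AUC-based sample size (Hanley-McNeil)
#'
#' Computes the number of patients needed to distinguish an alternative
#' AUC from a null AUC with given type I error and power, using the
#' Hanley-McNeil variance of a trapezoidal AUC. With
#' `Q1 = theta/(2 - theta)` and `Q2 = 2*theta^2/(1 + theta)`, the
#' large-sample per-positive variance with `kappa` negatives per positive
#' is `v(theta) = (Q1 - theta^2)/kappa + (Q2 - theta^2)`, and the number
#' of positives solves
#' `n = (z_{alpha/2} sqrt(v(theta0)) + z_beta sqrt(v(theta1)))^2 / (theta1 - theta0)^2`
#' (rounded up). The default `variance = "large_sample"` uses this closed
#' form; `variance = "small_sample"` instead searches for the smallest
#' group size satisfying the same inequality under the finite-sample
#' Hanley-McNeil variance
#' `[theta(1-theta) + (n_pos - 1)(Q1 - theta^2) + (n_neg - 1)(Q2 - theta^2)] / (n_pos n_neg)`,
#' which is slightly more conservative (it adds one pair of patients per
#' group at the default design). The enrollment figure inflates the total
#' by the dropout rate, rounded to the nearest integer.
#'
#' @param auc_alt Alternative-hypothesis AUC (default 0.75).
#' @param auc_null Null-hypothesis AUC (default 0.5).
#' @param alpha Two-sided type I error (default 0.05).
#' @param power Desired power (default 0.80).
#' @param allocation_ratio Negatives per positive (default 1).
#' @param dropout_rate Expected dropout fraction (default 0.10).
#' @param variance `"large_sample"` (default) or `"small_sample"`; see
#'   Details.
#' @return An object of class `sample_size_auc`: list with the inputs plus
#'   `n_pos`, `n_neg`, `n_per_group`, `n_total`, `n_enrolled`.
#' @examples
#' sample_size_auc()  # the default design: 19 + 19 = 38, enrol 42
#' @export
sample_size_auc <- function(auc_alt = 0.75, auc_null = 0.5,
                            alpha = 0.05, power = 0.80,
                            allocation_ratio = 1, dropout_rate = 0.10,
                            variance = c("large_sample", "small_sample")) {
  variance <- match.arg(variance)
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1))
    stop("need 0.5 <= auc_null < auc_alt < 1 (power unreachable otherwise)")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            allocation_ratio > 0, dropout_rate >= 0, dropout_rate < 1)
  q1 <- function(th) th / (2 - th)
  q2 <- function(th) 2 * th^2 / (1 + th)
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  delta <- auc_alt - auc_null
  kappa <- allocation_ratio

  if (variance == "large_sample") {
    v <- function(th) (q1(th) - th^2) / kappa + (q2(th) - th^2)
    n_pos <- ceiling((z_a * sqrt(v(auc_null)) + z_b * sqrt(v(auc_alt)))^2 / delta^2)
  } else {
    vfull <- function(th, np, nn)
      (th * (1 - th) + (np - 1) * (q1(th) - th^2) + (nn - 1) * (q2(th) - th^2)) / (np * nn)
    n_pos <- 2L
    repeat {
      nn <- ceiling(kappa * n_pos)
      lhs <- z_a * sqrt(vfull(auc_null, n_pos, nn)) +
        z_b * sqrt(vfull(auc_alt, n_pos, nn))
      if (lhs <= delta) break
      n_pos <- n_pos + 1L
      if (n_pos > 1e6) stop("sample-size search failed to converge")
    }
  }
  n_neg <- ceiling(kappa * n_pos)
  n_total <- n_pos + n_neg
  n_enrolled <- round(n_total * (1 + dropout_rate))
  structure(list(auc_alt = auc_alt, auc_null = auc_null, alpha = alpha,
                 power = power, allocation_ratio = allocation_ratio,
                 dropout_rate = dropout_rate, variance = variance,
                 n_pos = n_pos, n_neg = n_neg,
                 n_per_group = c(positives = n_pos, negatives = n_neg),
                 n_total = n_total, n_enrolled = n_enrolled),
            class = "sample_size_auc")
}

#' @export
print.sample_size_auc <- function(x, ...) {
  cat(sprintf(
    "<sample_size_auc> AUC %.2f vs %.2f, two-sided alpha %.3g, power %.2f (%s variance)\n",
    x$auc_alt, x$auc_null, x$alpha, x$power, x$variance))
  cat(sprintf("  %d positives + %d negatives = %d patients; enrol %d (dropout %.0f%%)\n",
              x$n_pos, x$n_neg, x$n_total, x$n_enrolled, 100 * x$dropout_rate))
  invisible(x)
}
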