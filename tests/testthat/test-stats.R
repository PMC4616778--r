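test_that("normality gate selects the documented test", {
  set.seed(41)
  a <- rnorm(20, 10, 1); b <- rnorm(20, 10.5, 1)
  g <- compare_groups(c(a, b), rep(c(TRUE, FALSE), each = 20), "continuous")
  expect_equal(g$test_used, "t_test")
  # heavy skew in one group forces the rank-sum test
  bs <- rexp(20)^3
  g2 <- compare_groups(c(a, bs), rep(c(TRUE, FALSE), each = 20), "continuous")
  expect_equal(g2$test_used, "mann_whitney")
  expect_lt(g2$normality_p[["group0"]], 0.05)
  # identical groups: t statistic 0, p = 1
  g3 <- compare_groups(c(a, a), rep(c(TRUE, FALSE), each = 20), "continuous")
  expect_equal(g3$statistic, 0, tolerance = 1e-12)
  expect_equal(g3$p_value, 1, tolerance = 1e-12)
  expect_error(compare_groups(a, rep(TRUE, 20), "continuous"), "empty")
  expect_error(compare_groups(c(a[1:2], b), rep(c(TRUE, FALSE), c(2, 20)),
                              "continuous"), "at least 3")
})

test_that("categorical comparisons switch to Fisher on sparse tables", {
  # 10/0 vs 0/10: all expected counts 5, but the enumeration is exact
  v <- rep(c("yes", "no"), each = 10)
  l <- rep(c(TRUE, FALSE), each = 10)
  g <- compare_groups(v, l, "categorical")
  expect_equal(g$test_used, "fisher_exact")
  expect_equal(g$p_value, fisher_enum(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(g$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # large balanced table goes to chi-square
  v2 <- rep(c("yes", "no", "yes", "no"), c(30, 20, 15, 35))
  l2 <- rep(c(TRUE, FALSE), each = 50)
  g2 <- compare_groups(v2, l2, "categorical")
  expect_equal(g2$test_used, "chi_square")
})

test_that("Fisher p equals hypergeometric enumeration across margins", {
  set.seed(42)
  for (i in 1:40) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c <- sample(0:8, 1); d <- sample(0:8, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    p_enum <- fisher_enum(a, b, c, d)
    p_r <- fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(p_r, p_enum, tolerance = 1e-9)
  }
})

test_that("group separation at reported effect size is reliably detected", {
  # Ea means 0.79 vs 0.61 with small SD, n = 17/22: significant in
  # nearly every replicate
  set.seed(43)
  hits <- replicate(400, {
    s <- simulate_binormal_scores(17, 22, sd_pos = 0.05)
    compare_groups(s$scores, s$labels, "continuous")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # 2 groups x 2 subjects x 2 times, worked by hand:
  # values chosen so each SS is a simple fraction
  d <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("A", "A", "B", "B"), each = 2),
    time = rep(c("t1", "t2"), 4),
    value = c(10, 12, 14, 18, 20, 26, 24, 32))
  # subject means: 11, 16, 23, 28 ; group means: 13.5, 25.5 ; grand 19.5
  # SS_group = 2*2*((13.5-19.5)^2 + (25.5-19.5)^2) = 288
  # SS_subj(group) = 2*((11-13.5)^2+(16-13.5)^2+(23-25.5)^2+(28-25.5)^2) = 50
  # time means: 17, 22 -> SS_time = 4*((17-19.5)^2+(22-19.5)^2) = 50
  # cell means: A(12,15), B(22,29): SS_int = 2*sum((cell - group - time + grand)^2)
  #   A,t1: +1 ; A,t2: -1 ; B,t1: -1 ; B,t2: +1 -> SS_int = 2*4 = 8
  # SS_total = sum((y-19.5)^2) = 398 -> residual = 398-288-50-50-8 = 2
  out <- rm_anova_two_way(d)
  expect_equal(out$F[out$effect == "group"], (288 / 1) / (50 / 2), tolerance = 1e-10)
  expect_equal(out$F[out$effect == "time"], (50 / 1) / (2 / 2), tolerance = 1e-10)
  expect_equal(out$F[out$effect == "group:time"], (8 / 1) / (2 / 2), tolerance = 1e-10)
  expect_equal(out$df_error[out$effect == "group"], 2)
  expect_equal(out$df_error[out$effect == "time"], 2)
})

test_that("degenerate ANOVA designs are handled explicitly", {
  d <- expand.grid(subject = paste0("s", 1:6), time = c("t1", "t2"))
  d$group <- rep(c("A", "B"), each = 3)[as.integer(gsub("s", "", d$subject))]
  d$value <- 5
  out <- rm_anova_two_way(d)
  expect_true(all(out$F == 0))
  expect_true(all(out$p == 1))
  # pure group offset with no noise: group F explodes, p underflows to 0
  d2 <- d
  d2$value <- ifelse(d2$group == "A", 5, 9)
  out2 <- rm_anova_two_way(d2)
  expect_true(is.infinite(out2$F[out2$effect == "group"]))
  expect_equal(out2$p[out2$effect == "group"], 0)
  # missing cell is an error, never imputed
  expect_error(rm_anova_two_way(d[-1, ]), "unbalanced")
})

test_that("null repeated-measures design gives uniform group p-values", {
  set.seed(44)
  ps <- replicate(200, {
    d <- expand.grid(subject = sprintf("s%02d", 1:10), time = paste0("t", 1:4))
    d$group <- rep(rep(c("A", "B"), each = 5), 4)
    d$value <- rnorm(10)[as.integer(factor(d$subject))] + rnorm(40)
    rm_anova_two_way(d)$p[1]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("AUC-based sample size reproduces the published design", {
  ss <- sample_size_auc()
  expect_equal(ss$n_total, 38)      # 19 + 19 for AUC 0.75 vs 0.5
  expect_equal(ss$n_enrolled, 42)   # 10% dropout, rounded
  # the finite-sample variance variant is deliberately more conservative
  ss2 <- sample_size_auc(variance = "small_sample")
  expect_gte(ss2$n_total, ss$n_total)
})

test_that("sample size is monotone in effect size and alpha", {
  n_at <- function(alt, alpha = 0.05)
    sample_size_auc(auc_alt = alt, alpha = alpha)$n_total
  expect_true(all(diff(sapply(c(0.65, 0.75, 0.85, 0.95), n_at)) < 0))
  expect_gte(n_at(0.75, 0.01), n_at(0.75, 0.05))
  expect_error(sample_size_auc(auc_alt = 0.5), "auc_null < auc_alt")
})
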