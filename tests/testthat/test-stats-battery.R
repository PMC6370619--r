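test_that("test routing follows Shapiro-Wilk normality", {
  set.seed(1)
  expect_equal(route_test(rnorm(60), rnorm(60, 1)), "t-test")
  expect_equal(route_test(rlnorm(60, 0, 1.5), rnorm(60)), "mann-whitney")
  expect_warning(r2 <- route_test(c(1, 2), c(3, 4)), "n < 3")
  expect_equal(r2, "mann-whitney")
  expect_equal(route_test(rnorm(50), rnorm(50), for_correlation = TRUE),
               "pearson")
})

test_that("pooled t-test reproduces the published age comparison", {
  # printed group summaries: AIR 38.1 +/- 8.6 (n=14), PIR 45.3 +/- 10.8 (n=19)
  d <- cohens_d_pooled(38.1, 8.6, 14, 45.3, 10.8, 19)
  expect_equal(round(d, 2), 0.72)
  expect_equal(magnitude_label("cohens_d", d), "medium")
  # pooled df convention: t(31) = 14 + 19 - 2
  set.seed(2)
  res <- independent_t(rnorm(14, 38.1, 8.6), rnorm(19, 45.3, 10.8))
  expect_equal(res$df, 31)
  a <- rnorm(10)
  same <- independent_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$effect, 0)
  expect_equal(cohens_d_pooled(0, 1, 20, 1, 1, 20), 1)
  expect_equal(cohens_d_pooled(3, 1, 5, 3, 1, 9), 0)
  expect_error(cohens_d_pooled(1, 0, 5, 2, 0, 5), "pooled SD")
})

test_that("paired Cohen's d uses the SD of the differences", {
  expect_equal(paired_d(c(2, 4, 6) - c(1, 2, 3)), mean(1:3) / sd(1:3))
  expect_error(paired_d(c(1, 1, 1)), "SD")
})

test_that("Mann-Whitney U, exact p and signed r follow the stated conventions", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_lt(res$effect, 0)

  # complementarity U_a + U_b = n_a * n_b, with and without ties
  set.seed(17)
  for (i in 1:20) {
    a <- sample(1:8, sample(2:10, 1), replace = TRUE)
    b <- sample(1:8, sample(2:10, 1), replace = TRUE)
    ua <- mann_whitney(a, b)$statistic
    ub <- mann_whitney(b, a)$statistic
    expect_equal(ua + ub, length(a) * length(b))
  }
  # identical samples: no effect
  x <- c(1, 5, 5, 9)
  expect_equal(mann_whitney(x, x)$effect, 0)

  # agrees with the reference implementation on tie-free samples
  set.seed(18)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    expect_equal(mann_whitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # signed r = Z / sqrt(N): reproduces the printed magnitude for U = 203
  # with groups of 14 and 19 (the baseline viral-load comparison)
  z <- (203 - 14 * 19 / 2) / sqrt(14 * 19 * (14 + 19 + 1) / 12)
  expect_equal(round(abs(z) / sqrt(33), 2), 0.44)
})

test_that("Fisher exact test reproduces the published 2x2 comparisons", {
  # HCV: 7/19 PIR vs 2/14 AIR exposed
  hcv <- fisher_exact_2x2(matrix(c(7, 2, 12, 12), 2))
  expect_equal(round(hcv$effect, 2), 3.50)
  # gender: 9/14 AIR male vs 14/19 PIR male
  gender <- fisher_exact_2x2(matrix(c(9, 14, 5, 5), 2))
  expect_equal(round(gender$effect, 2), 0.64)
  # drug resistance among patients with known status
  res <- fisher_exact_2x2(matrix(c(3, 8, 11, 10), 2))
  expect_equal(round(res$effect, 2), 0.34)
  # p-values agree with the reference implementation
  for (tab in list(matrix(c(7, 2, 12, 12), 2), matrix(c(9, 14, 5, 5), 2),
                   matrix(c(3, 8, 11, 10), 2), matrix(c(2, 0, 0, 2), 2))) {
    expect_equal(fisher_exact_2x2(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 1, 2), 2))$effect, Inf)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Cramer's V matches direct chi-square arithmetic", {
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2)), 1)
  indep <- outer(c(12, 18), c(5, 10, 15)) / 30
  expect_equal(cramers_v(indep), 0)
  tab <- matrix(c(8, 2, 5, 5, 1, 9), nrow = 3, byrow = TRUE)
  chisq <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  expect_equal(cramers_v(tab), sqrt(unname(chisq) / (sum(tab) * 1)),
               tolerance = 1e-12)
  expect_error(cramers_v(matrix(1:3, 1)), "degenerate")
})

test_that("magnitude labels are exact step functions of the printed bins", {
  expect_equal(magnitude_label("cohens_d", 0.29), "small")
  expect_equal(magnitude_label("cohens_d", 0.30), "medium")
  expect_equal(magnitude_label("cohens_d", 0.72), "medium")
  expect_equal(magnitude_label("cohens_d", 0.80), "large")
  expect_equal(magnitude_label("rank_r", -0.44), "medium")
  expect_equal(magnitude_label("rank_r", 0.50), "large")
  expect_equal(magnitude_label("cramers_v", 0.70), "medium")
  expect_equal(magnitude_label("cramers_v", 0.71), "large")
  expect_equal(magnitude_label("correlation", 0.95), "very high")
  expect_equal(magnitude_label("correlation", 0.69), "moderate")
  expect_error(magnitude_label("banana", 0.5), "unknown")
})

test_that("Bonferroni thresholds match the figure-family corrections", {
  expect_equal(round(bonferroni_flags(0.01, m = 14)$threshold, 3), 0.004)
  expect_equal(bonferroni_flags(0.01, m = 5)$threshold, 0.010)
  expect_equal(bonferroni_flags(0.02, m = 1)$threshold, 0.05)
  bf <- bonferroni_flags(c(0.001, 0.004, 0.01), alpha = 0.05, m = 14)
  expect_equal(bf$flags, c(TRUE, FALSE, FALSE))
  expect_error(bonferroni_flags(0.1, m = 0), "m")
})

test_that("extreme outlier fences use 3 IQR under interpolated quartiles", {
  f <- extreme_outlier_fence(c(1:8, 1000))
  expect_equal(unname(f$is_extreme), c(rep(FALSE, 8), TRUE))
  q <- quantile(c(1:8, 1000), c(0.25, 0.75), type = 7)
  expect_equal(f$upper, unname(q[2] + 3 * (q[2] - q[1])))
  expect_equal(f$quartile_type, "linear interpolation (type 7)")
  sens <- extreme_outlier_sensitivity(mann_whitney, c(1:8, 1000), 1:9)
  expect_true(sens$n_removed[["a"]] == 1 && sens$n_removed[["b"]] == 0)
  # a clean symmetric sample is untouched and results are identical
  a <- c(-2, -1, 0, 1, 2); b <- c(-1, 0, 1, 2, 3)
  sens2 <- extreme_outlier_sensitivity(mann_whitney, a, b)
  expect_identical(sens2$with_outliers$p, sens2$without_outliers$p)
  expect_true(sens2$agree)
})

test_that("interval CD4 slopes are least squares on all visits in the window", {
  expect_equal(cd4_slope(series_df(c(0, 2), c(100, 200)), 0, 2), 50)
  expect_equal(cd4_slope(series_df(c(0, 6, 12), c(0, 60, 120)), 0, 12), 10)
  s <- series_df(c(2, 6, 12), c(100, 120, 150))
  expect_equal(cd4_slope(s, 2, 12),
               unname(coef(lm(value ~ time_months, s))[2]), tolerance = 1e-12)
  # endpoints are inclusive and out-of-window visits ignored
  s2 <- series_df(c(0, 2, 6, 12), c(100, 200, 220, 900))
  expect_equal(cd4_slope(s2, 0, 2), 50)
  expect_true(is.na(cd4_slope(s2, 20, 24)))
})

test_that("thymic score is the product of the volume and index means", {
  expect_equal(thymic_score(c(10, 14), c(2, 3)), 30)
  expect_equal(thymic_score(8, 3), 24)
  expect_equal(thymic_score(c(10, 14), c(0, 0)), 0)
  expect_error(thymic_score(numeric(0), 2), "at least one")
})

test_that("derived features follow their unit definitions", {
  visits <- rbind(
    data.frame(patient_id = "P1", time_months = 6,
               analyte = c("cd4_count", "cd8_count", "rte_pct",
                           "sj_trec_per1e5", "dj_trec_per1e5"),
               value = c(400, 800, 20, 3000, 300)),
    data.frame(patient_id = "P2", time_months = 6,
               analyte = c("cd4_count", "cd8_count"), value = c(300, 0)))
  feats <- derived_features(visits, pbmc_per_ml = 1e6)
  p1 <- feats[feats$patient_id == "P1", ]
  expect_equal(p1$rte_abs, 80)                   # 20% of 400 cells/uL
  expect_equal(p1$cd4_cd8_ratio, 0.5)
  expect_equal(p1$sj_beta_ratio, 10)             # 3000 / 300
  expect_equal(p1$trec_per_ml, 3000 * 1e6 / 1e5)
  p2 <- feats[feats$patient_id == "P2", ]
  expect_true(is.na(p2$cd4_cd8_ratio))           # zero CD8 flagged undefined
  expect_equal(unname(attr(feats, "n_undefined")[["ratio"]]), 1L)
})
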