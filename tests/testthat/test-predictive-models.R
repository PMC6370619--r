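toy_outcome_data <- function(n = 200, beta = 2, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  noise <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + beta * x))
  data.frame(y = y, x = x, noise = noise)
}

test_that("logistic fitting handles the closed-form and degenerate cases", {
  d <- data.frame(y = rep(c(1, 0), c(14, 19)))
  fit <- fit_logistic(d, "y")
  expect_equal(unname(fitted(fit$glm)), rep(14 / 33, 33), tolerance = 1e-9)
  expect_equal(fit$n, 33)

  sep <- data.frame(y = c(0, 0, 1, 1), x = c(-2, -1, 1, 2))
  fit_sep <- fit_logistic(sep, "y", "x")
  expect_true(fit_sep$separation)

  expect_error(fit_logistic(data.frame(y = rep(1, 10), x = rnorm(10)),
                            "y", "x"), "constant outcome")
  dd <- data.frame(y = rep(0:1, 10), x = 1:20, x2 = 2 * (1:20))
  expect_error(fit_logistic(dd, "y", c("x", "x2")), "rank-deficient")
  # complete cases are dropped and counted
  d2 <- toy_outcome_data(50)
  d2$x[1:5] <- NA
  fit2 <- fit_logistic(d2, "y", "x")
  expect_equal(fit2$n_dropped, 5)
  expect_equal(fit2$n, 45)
})

test_that("maximum likelihood matches a brute-force likelihood grid oracle", {
  # overlapping classes, so the MLE is finite
  d <- data.frame(y = c(0, 1, 0, 1, 1, 0),
                  x = c(-1.5, -0.5, 0.3, 0.8, 1.2, 2.0))
  fit <- fit_logistic(d, "y", "x")
  expect_false(fit$separation)
  ll <- function(b0, b1) sum(dbinom(d$y, 1, plogis(b0 + b1 * d$x),
                                    log = TRUE))
  search <- function(b0s, b1s) {
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    grid[which.max(mapply(ll, grid$b0, grid$b1)), ]
  }
  coarse <- search(seq(-4, 4, by = 0.05), seq(-4, 4, by = 0.05))
  best <- search(seq(coarse$b0 - 0.1, coarse$b0 + 0.1, by = 0.001),
                 seq(coarse$b1 - 0.1, coarse$b1 + 0.1, by = 0.001))
  expect_lt(abs(fit$coefficients["(Intercept)", "estimate"] - best$b0), 2e-3)
  expect_lt(abs(fit$coefficients["x", "estimate"] - best$b1), 2e-3)
})

test_that("univariable screen retains signal and rejects noise at the 0.20 level", {
  d <- toy_outcome_data(300, beta = 2, seed = 5)
  scr <- univariable_screen(d, "y", c("x", "noise"))
  expect_true(scr$retained[scr$candidate == "x"])
  expect_equal(nrow(scr), 2)

  # type-I behaviour of the liberal screen on pure noise
  set.seed(6)
  rejected <- vapply(1:200, function(i) {
    dd <- data.frame(y = rbinom(80, 1, 0.45), z = rnorm(80))
    !suppressWarnings(univariable_screen(dd, "y", "z")$retained)
  }, logical(1))
  expect_gt(mean(rejected), 0.71)
  expect_lt(mean(rejected), 0.89)

  # a candidate identical to the outcome separates; retained with a warning
  d$same <- d$y
  expect_warning(scr2 <- univariable_screen(d, "y", "same"), "separation")
  expect_true(scr2$retained)
})

test_that("backward stepwise removes the least significant predictor first", {
  removed_noise_first <- vapply(1:50, function(i) {
    d <- toy_outcome_data(500, beta = 1.5, seed = 100 + i)
    fit <- backward_stepwise(d, "y", c("x", "noise"))
    length(fit$removal_trace) >= 1 && fit$removal_trace[1] == "noise"
  }, logical(1))
  expect_gte(mean(removed_noise_first), 0.9)

  d <- toy_outcome_data(500, beta = 2, seed = 3)
  d$x2 <- rbinom(500, 1, plogis(d$x)) + rnorm(500)  # second real-ish signal
  fit <- backward_stepwise(d, "y", c("x"))
  expect_equal(fit$removal_trace, character(0))     # all significant: no-op
  fit2 <- backward_stepwise(d, "y", c("x", "noise", "x2"))
  expect_equal(length(fit2$removal_trace),
               3 - length(fit2$predictors))
})

test_that("likelihood ratio test is non-negative, nested-only and null-uniform", {
  d <- toy_outcome_data(150, seed = 9)
  full <- fit_logistic(d, "y", c("x", "noise"))
  red <- fit_logistic(d, "y", "x")
  lrt <- likelihood_ratio_test(red, full)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(likelihood_ratio_test(fit_logistic(d, "y", "noise"), red),
               "not nested")

  # adding a pure-noise column gives a uniform LRT p under the null
  set.seed(10)
  ps <- vapply(1:200, function(i) {
    dd <- toy_outcome_data(100, seed = 2000 + i)
    likelihood_ratio_test(fit_logistic(dd, "y", "x"),
                          fit_logistic(dd, "y", c("x", "noise")))$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("AIC comparison requires a common dataset and penalizes noise", {
  d <- toy_outcome_data(120, seed = 11)
  m1 <- fit_logistic(d, "y", "x")
  m2 <- fit_logistic(d, "y", c("x", "noise"))
  cmp <- compare_aic(base = m1, noisy = m2)
  expect_equal(cmp$aic, sort(cmp$aic))
  expect_equal(compare_aic(a = m1, b = m1)$aic[1], compare_aic(a = m1, b = m1)$aic[2])

  d2 <- d[-1, ]
  m3 <- fit_logistic(d2, "y", "x")
  expect_error(compare_aic(a = m1, b = m3), "different observations")

  # expected AIC penalty of an irrelevant predictor is positive
  set.seed(12)
  deltas <- vapply(1:100, function(i) {
    dd <- toy_outcome_data(100, seed = 3000 + i)
    fit_logistic(dd, "y", c("x", "noise"))$aic - fit_logistic(dd, "y", "x")$aic
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("Hosmer-Lemeshow is zero for perfectly calibrated bins and null-uniform", {
  p <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  y <- unlist(lapply(seq(0.05, 0.95, by = 0.1), function(pr) {
    rep(c(1, 0), c(round(20 * pr), 20 - round(20 * pr)))
  }))
  hl <- hosmer_lemeshow(p, y, g = 10)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$df, 8)
  expect_error(hosmer_lemeshow(runif(5), rbinom(5, 1, 0.5), g = 10),
               "at least g")
  expect_error(hosmer_lemeshow(runif(20), rbinom(20, 1, 0.5), g = 1), "g")

  set.seed(13)
  ps <- vapply(1:200, function(i) {
    x <- rnorm(250)
    y <- rbinom(250, 1, plogis(-0.5 + x))
    fit <- glm(y ~ x, family = binomial())
    hosmer_lemeshow(fitted(fit), y)$p
  }, numeric(1))
  # roughly uniform: nominal rejection close to 5%
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("trapezoidal AUC equals the rank statistic and labels follow the bins", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(0:1, 5))$auc, 0.5)
  set.seed(14)
  scores <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  r <- roc_auc(scores, y)
  u <- mann_whitney(scores[y == 1], scores[y == 0])$statistic
  expect_equal(r$auc, u / (sum(y) * sum(1 - y)), tolerance = 1e-12)
  expect_equal(r$auc, as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, scores, quiet = TRUE, direction = "<",
                        levels = c(0, 1))))), tolerance = 1e-12)
  expect_equal(roc_auc(c(1, 1, 0, 0.4), c(1, 1, 0, 0))$label, "excellent")
  expect_error(roc_auc(runif(5), rep(1, 5)), "both")
})

test_that("the 0.5 rule and the sensitivity/specificity/accuracy definitions hold", {
  labs <- rep(c("PIR", "AIR"), c(3, 2))
  perfect <- classify_and_tabulate(c(1, 1, 1, 0, 0), labs)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  # a probability of exactly 0.5 is called "probably PIR"
  boundary <- classify_and_tabulate(0.5, "PIR")
  expect_equal(boundary$calls, "probably PIR")
  mixed <- classify_and_tabulate(c(0.9, 0.2, 0.6, 0.4), c("PIR", "PIR",
                                                          "AIR", "AIR"))
  expect_equal(mixed$sensitivity, 50)
  expect_equal(mixed$specificity, 50)
  expect_equal(mixed$accuracy, 50)
  expect_error(classify_and_tabulate(1.2, "PIR"), "\\[0, 1\\]")
})

test_that("published coefficient models evaluate the printed formula", {
  models <- published_models()
  expect_length(models, 4)
  expect_equal(models$model3$a, -9.703)
  expect_equal(models$model4$d, 0.012)
  expect_equal(models$model1$n, 31)

  cov <- data.frame(age_years = 45, log10_vl_baseline = 5.0,
                    cd4_count_6mo = 200)
  ev <- evaluate_published_model("model3", cov)
  # eta = -9.703 - 0.103*45 + 1.897*5 + 0.013*200 = -2.253
  expect_equal(ev$p_pir, 1 / (1 + exp(-2.253)), tolerance = 1e-9)
  expect_equal(round(ev$p_pir, 3), 0.905)
  expect_equal(ev$call, "probably PIR")

  zero <- list(name = "null", a = 0, b = 0, c = 0, d = 0,
               predictors = models$model3$predictors)
  expect_equal(evaluate_published_model(zero, cov)$p_pir, 0.5)

  # monotonicity: higher 6-month CD4 lowers P(PIR) under model 3 (d > 0)
  cd4 <- seq(50, 600, by = 50)
  cov_m <- data.frame(age_years = 45, log10_vl_baseline = 5.0,
                      cd4_count_6mo = cd4)
  expect_true(all(diff(evaluate_published_model("model3", cov_m)$p_pir) < 0))

  expect_error(evaluate_published_model("model3",
                                        data.frame(age_years = 45)),
               "lack predictor")
  cov_na <- data.frame(age_years = c(45, NA), log10_vl_baseline = 5,
                       cd4_count_6mo = 200)
  expect_message(ev_na <- evaluate_published_model("model3", cov_na),
                 "missing")
  expect_true(is.na(ev_na$p_pir[2]) && is.na(ev_na$call[2]))
})

test_that("early-timepoint predictors are assembled on the study units", {
  co <- generate_cohort(cohort_config(covariates =
                                        covariate_model(missing_prob = 0)),
                        seed = 15)
  pred <- predictor_table(co)
  expect_setequal(
    c("age_years", "log10_vl_baseline", "cd4_count_2mo", "cd4_count_6mo",
      "cd4_slope_0_6", "rte_pct_6mo", "rte_ratio_0_6mo"),
    setdiff(names(pred), "patient_id"))
  p1 <- pred[1, ]
  s1 <- visit_series(co, p1$patient_id, "cd4_count")
  expect_equal(p1$cd4_count_2mo, s1$value[s1$time_months == 2])
  expect_equal(p1$cd4_slope_0_6, cd4_slope(s1, 0, 6))
  r1 <- visit_series(co, p1$patient_id, "rte_pct")
  expect_equal(p1$rte_ratio_0_6mo,
               r1$value[r1$time_months == 0] / r1$value[r1$time_months == 6])
})
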