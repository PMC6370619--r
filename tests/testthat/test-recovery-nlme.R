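test_that("noise-free cohorts return the generating parameters", {
  co <- generate_cohort(noise_free_config(), seed = 1)
  lab <- true_labels(co)
  fit <- fit_recovery_nlme(co, lab, "cd4_count", "study-cd4")
  expect_equal(unname(fit$A), c(130.1, 130.1), tolerance = 1e-3)
  expect_equal(unname(fit$B), c(499.0, 284.5), tolerance = 1e-3)
  expect_equal(unname(fit$tau), c(17.6, 31.9), tolerance = 1e-3)
  expect_equal(unname(fit$asymptote), c(629.1, 414.6), tolerance = 1e-3)
  expect_true(fit$converged)

  rfit <- fit_recovery_nlme(co, lab, "cd4_cd8_ratio", "study-ratio")
  expect_equal(unname(rfit$B), c(0.644, 0.475), tolerance = 1e-3)
  expect_equal(unname(rfit$tau), c(27.620, 27.620), tolerance = 1e-3)
})

test_that("fixed effects are recovered from a noisy 200-patient cohort", {
  cfg <- cohort_config(n_air = 100, n_pir = 100)
  co <- generate_cohort(cfg, seed = 7)
  fit <- fit_recovery_nlme(co, true_labels(co), "cd4_count", "study-cd4")
  expect_true(fit$converged)
  expect_equal(fit$A[["AIR"]], 130.1, tolerance = 0.15)
  expect_equal(fit$B[["AIR"]], 499.0, tolerance = 0.15)
  expect_equal(fit$B[["PIR"]], 284.5, tolerance = 0.15)
  expect_equal(fit$tau[["AIR"]], 17.6, tolerance = 0.15)
  expect_equal(fit$tau[["PIR"]], 31.9, tolerance = 0.15)
  # random-effect covariance has the configured scales
  expect_equal(sqrt(fit$ranef_cov["A", "A"]), 60, tolerance = 0.35)
  expect_equal(sqrt(fit$ranef_cov["B", "B"]), 120, tolerance = 0.35)
  expect_equal(fit$sigma, 50, tolerance = 0.15)
})

test_that("a single-group shared-effect fit matches a brute-force grid+profile oracle", {
  # 5-patient toy set, all fixed effects shared, random intercept only: given
  # tau the marginal covariance is compound-symmetric, so the oracle profiles
  # (A, B) by GLS and maximizes the exact likelihood on a (tau, sigma_a,
  # sigma_e) grid
  set.seed(33)
  times <- c(0, 2, 6, 12, 24, 36)
  pats <- sprintf("T%d", 1:5)
  a_i <- rnorm(5, 200, 30)
  visits <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(patient_id = pats[i], time_months = times, analyte = "cd4_count",
               value = a_i[i] + 300 * (1 - exp(-times / 10)) + rnorm(6, 0, 15))
  }))
  labels <- data.frame(patient_id = pats, label = "ALL")

  oracle <- function(tau_grid, sa_grid, se_grid) {
    n_t <- length(times)
    best <- list(ll = -Inf)
    y <- visits$value
    for (tau in tau_grid) {
      f <- 1 - exp(-times / tau)
      X <- cbind(1, f)
      for (sa in sa_grid) for (se in se_grid) {
        Vi <- sa^2 + diag(se^2, n_t)     # per-patient covariance
        Vinv <- solve(Vi)
        XtVX <- matrix(0, 2, 2); XtVy <- numeric(2); ll_const <- 0
        for (i in 1:5) {
          yi <- y[visits$patient_id == pats[i]]
          XtVX <- XtVX + t(X) %*% Vinv %*% X
          XtVy <- XtVy + t(X) %*% Vinv %*% yi
        }
        beta <- solve(XtVX, XtVy)
        ll <- 0
        for (i in 1:5) {
          r <- y[visits$patient_id == pats[i]] - X %*% beta
          ll <- ll - 0.5 * (determinant(Vi)$modulus +
                              t(r) %*% Vinv %*% r + n_t * log(2 * pi))
        }
        if (ll > best$ll) best <- list(ll = as.numeric(ll), tau = tau,
                                       beta = as.numeric(beta))
      }
    }
    best
  }
  coarse <- oracle(seq(4, 30, by = 1), seq(5, 80, by = 5), seq(5, 40, by = 2.5))
  fine <- oracle(seq(coarse$tau - 1, coarse$tau + 1, by = 0.05),
                 seq(5, 80, by = 2), seq(5, 40, by = 1))

  spec <- kinetic_model_spec(A = "shared", B = "shared", tau = "shared",
                             random = "A")
  fit <- fit_recovery_nlme(visits, labels, "cd4_count", spec)
  expect_equal(fit$tau[["ALL"]], fine$tau, tolerance = 0.01)
  expect_equal(fit$A[["ALL"]], fine$beta[1], tolerance = 0.01)
  expect_equal(fit$B[["ALL"]], fine$beta[2], tolerance = 0.01)
})

test_that("rescaling time months -> days rescales tau and leaves A, B invariant", {
  co <- generate_cohort(cohort_config(), seed = 13)
  lab <- true_labels(co)
  fit_m <- fit_recovery_nlme(co, lab, "cd4_count", "study-cd4")
  days <- co
  days$visits$time_months <- days$visits$time_months * 30.44
  fit_d <- fit_recovery_nlme(days$visits, lab, "cd4_count", "study-cd4")
  # tolerance reflects the outer optimizer's own tolerance at two scales
  expect_equal(unname(fit_d$A), unname(fit_m$A), tolerance = 1e-2)
  expect_equal(unname(fit_d$B), unname(fit_m$B), tolerance = 1e-2)
  expect_equal(unname(fit_d$tau), unname(fit_m$tau) * 30.44,
               tolerance = 1e-2)
})

test_that("mean curve prediction is anchored at A and reaches the plateau", {
  co <- generate_cohort(noise_free_config(), seed = 2)
  fit <- fit_recovery_nlme(co, true_labels(co), "cd4_count", "study-cd4")
  for (g in c("AIR", "PIR")) {
    curve0 <- predict_mean_curve(fit, g, 0)
    expect_equal(curve0$value, fit$A[[g]])
    far <- predict_mean_curve(fit, g, 10 * fit$tau[[g]])
    expect_equal(far$value, fit$asymptote[[g]],
                 tolerance = 5e-5)
    t600 <- predict_mean_curve(fit, g, 600)$value
    expect_equal(t600, c(AIR = 629.1, PIR = 414.6)[[g]], tolerance = 0.5 / 400)
    curve <- predict_mean_curve(fit, g, seq(0, 60, by = 2))
    expect_true(all(diff(curve$value) >= 0))
  }
  expect_error(predict_mean_curve(fit, "XYZ", 0), "unknown group")
})

test_that("model frame validation rejects degenerate inputs", {
  co <- generate_cohort(cohort_config(), seed = 21)
  lab <- true_labels(co)
  expect_error(fit_recovery_nlme(co, lab[-1, ], "cd4_count"), "without a group")
  v <- co$visits[co$visits$time_months == 0, ]
  expect_error(fit_recovery_nlme(v, lab, "cd4_count"), ">= 3 visits")
  expect_error(fit_recovery_nlme(co, lab, "nonexistent_analyte"), "no")
  one_group <- lab
  one_group$label[1] <- "LONER"
  one_group$label[-1] <- "REST"
  expect_error(fit_recovery_nlme(co, one_group, "cd4_count"), ">= 2 patients")
})
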