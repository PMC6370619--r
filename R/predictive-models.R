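#' Fit a logistic regression for the AIR/PIR outcome
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of a binary
#' outcome coded `Y = 1` for AIR, `Y = 0` for PIR, on the given predictors.
#' Rows with missing predictors are dropped as complete cases and counted.
#' Complete or quasi-complete separation is detected and reported as a flag,
#' never silently.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome name of the binary outcome column (0/1 or logical).
#' @param predictors character vector of predictor column names; empty for an
#'   intercept-only model.
#' @return object of class `"logistic_fit"`: `glm` (the underlying fit),
#'   `coefficients` (estimate, SE, z, Wald p), `logLik`, `aic`, `n`,
#'   `rows` (row names used), `n_dropped`, `separation`, `predictors`.
#' @export
fit_logistic <- function(data, outcome, predictors = character(0)) {
  if (!outcome %in% names(data)) stop("outcome column '", outcome, "' absent")
  cols <- c(outcome, predictors)
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[cc, cols, drop = FALSE]
  y <- as.numeric(d[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stop("constant outcome: both classes required")
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  form <- stats::as.formula(paste(outcome, "~", rhs))
  if (length(predictors)) {
    X <- stats::model.matrix(form, d)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = d),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("did not converge", msg)) {
        # surfaced through the separation/convergence flag instead
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) separation <- TRUE
  cf <- summary(fit)$coefficients
  colnames(cf) <- c("estimate", "se", "z", "p")
  structure(list(glm = fit, coefficients = cf,
                 logLik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), n = nrow(d),
                 rows = rownames(d), n_dropped = sum(!cc),
                 separation = separation, outcome = outcome,
                 predictors = predictors),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (%s ~ %s): n = %d (%d dropped), AIC = %.2f%s\n",
              x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1",
              x$n, x$n_dropped, x$aic,
              if (x$separation) " [separation detected]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Univariable predictor screen
#'
#' Fits one single-predictor logistic model per candidate and retains those
#' with coefficient p-value below `p_threshold` (0.20, a deliberately liberal
#' screen). Wald p by default; the likelihood-ratio p is available. A
#' candidate causing separation is retained with a warning.
#'
#' @inheritParams fit_logistic
#' @param candidates character vector of candidate predictor columns.
#' @param p_threshold retention threshold on the coefficient p-value.
#' @param type `"wald"` or `"lrt"`.
#' @return data.frame `candidate`, `p`, `separation`, `retained`.
#' @export
univariable_screen <- function(data, outcome, candidates, p_threshold = 0.20,
                               type = c("wald", "lrt")) {
  type <- match.arg(type)
  res <- lapply(candidates, function(v) {
    fit <- fit_logistic(data, outcome, v)
    p <- if (type == "wald") fit$coefficients[v, "p"] else {
      null <- fit_logistic(data[fit$rows, , drop = FALSE], outcome,
                           character(0))
      likelihood_ratio_test(null, fit)$p
    }
    if (fit$separation) {
      warning("separation on candidate '", v, "'; retained with flag")
      p <- 0
    }
    data.frame(candidate = v, p = p, separation = fit$separation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$retained <- out$p < p_threshold
  rownames(out) <- NULL
  out
}

#' Backward stepwise elimination by coefficient significance
#'
#' Starting from all retained variables, repeatedly removes the predictor with
#' the largest Wald p-value at or above `p_remove` and refits, until every
#' remaining coefficient is significant or a single predictor remains. The
#' removal order is recorded.
#'
#' @inheritParams fit_logistic
#' @param variables starting predictor set.
#' @param p_remove removal threshold on the Wald p (default 0.05).
#' @return the final `"logistic_fit"`, with a `removal_trace` element
#'   (character vector, possibly empty) and `initial_variables`.
#' @export
backward_stepwise <- function(data, outcome, variables, p_remove = 0.05) {
  if (!length(variables)) stop("need at least one starting variable")
  vars <- variables
  trace <- character(0)
  repeat {
    fit <- fit_logistic(data, outcome, vars)
    pw <- fit$coefficients[setdiff(rownames(fit$coefficients), "(Intercept)"),
                           "p", drop = TRUE]
    names(pw) <- setdiff(rownames(fit$coefficients), "(Intercept)")
    if (length(vars) == 1 || max(pw) < p_remove) break
    drop_var <- names(pw)[which.max(pw)]
    trace <- c(trace, drop_var)
    vars <- setdiff(vars, drop_var)
  }
  fit$removal_trace <- trace
  fit$initial_variables <- variables
  fit
}

#' Likelihood ratio test between nested logistic fits
#'
#' `LR = 2 (logLik_full - logLik_reduced)`, referred to a chi-square with df
#' equal to the parameter difference. Requires the reduced model's predictors
#' to be a subset of the full model's and both fits to use the same rows. A
#' non-significant p endorses the reduced model.
#'
#' @param reduced,full `"logistic_fit"` objects.
#' @return list `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(reduced, full) {
  if (!all(reduced$predictors %in% full$predictors)) {
    stop("models are not nested (reduced predictors not a subset)")
  }
  if (!identical(sort(reduced$rows), sort(full$rows))) {
    stop("models were fitted on different rows; subset to complete cases")
  }
  df <- length(full$predictors) - length(reduced$predictors)
  stat <- max(2 * (full$logLik - reduced$logLik), 0)
  list(statistic = stat, df = df,
       p = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Rank models by AIC on a common complete-case dataset
#'
#' Refuses to compare fits that used different observation sets, mirroring the
#' practice of rebuilding all candidate models on one fixed dataset with no
#' missing values before AIC comparison.
#'
#' @param ... named `"logistic_fit"` objects (or a single list of them).
#' @return data.frame `model`, `aic`, `logLik`, `n_params`, ranked by
#'   ascending AIC.
#' @export
compare_aic <- function(...) {
  models <- list(...)
  if (length(models) == 1 && !inherits(models[[1]], "logistic_fit")) {
    models <- models[[1]]
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("model", seq_along(models))
  }
  rows <- lapply(models, function(m) sort(m$rows))
  if (!all(vapply(rows, identical, logical(1), rows[[1]]))) {
    stop("models use different observations; refit on common complete cases")
  }
  out <- data.frame(
    model = names(models),
    aic = vapply(models, `[[`, numeric(1), "aic"),
    logLik = vapply(models, `[[`, numeric(1), "logLik"),
    n_params = vapply(models, function(m) length(m$predictors) + 1,
                      numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  out
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping: observations are binned into `g` equal-count
#' groups by predicted probability (ties kept together), and the chi-square
#' statistic over the `2g` observed/expected cells is referred to
#' chi-square(g - 2).
#'
#' @param probabilities fitted event probabilities.
#' @param outcomes observed 0/1 outcomes.
#' @param g number of risk groups (default 10).
#' @return list `statistic`, `df`, `p`, `table` (per-bin observed/expected).
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, g = 10) {
  if (g < 2) stop("'g' must be >= 2")
  n <- length(probabilities)
  if (n < g) stop("need at least g observations")
  if (length(outcomes) != n) stop("length mismatch")
  y <- as.numeric(outcomes)
  breaks <- unique(stats::quantile(probabilities, probs = seq(0, 1, 1 / g),
                                   type = 7))
  bin <- cut(probabilities, breaks = breaks, include.lowest = TRUE)
  obs1 <- tapply(y, bin, sum)
  exp1 <- tapply(probabilities, bin, sum)
  nn <- tapply(y, bin, length)
  keep <- !is.na(nn)
  obs1 <- obs1[keep]; exp1 <- exp1[keep]; nn <- nn[keep]
  stat <- sum((obs1 - exp1)^2 / exp1 + ((nn - obs1) - (nn - exp1))^2 /
                (nn - exp1))
  df <- length(nn) - 2
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(n = as.vector(nn), observed = as.vector(obs1),
                          expected = as.vector(exp1)))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps all score thresholds, returns the ROC points and the area under the
#' curve by trapezoidal integration — numerically identical to the
#' Mann-Whitney pair-win probability `U/(n1 n0)` (ties counting one half).
#' Quality labels: poor < 0.7, fair \[0.7, 0.8), good \[0.8, 0.9\],
#' excellent > 0.9.
#'
#' @param scores predicted probabilities (or any monotone risk score) for the
#'   positive class.
#' @param outcomes observed 0/1 class indicators.
#' @return list `auc`, `label`, `roc` (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, outcomes) {
  y <- as.numeric(outcomes)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)   # one ROC point per threshold
  roc <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  label <- if (auc > 0.9) "excellent" else if (auc >= 0.8) "good" else
    if (auc >= 0.7) "fair" else "poor"
  list(auc = auc, label = label, roc = roc)
}

#' Classify patients by the 0.5 rule and tabulate performance
#'
#' Patients with predicted probability of being PIR at or above 0.5 are called
#' "probably PIR", the rest "probably AIR". Sensitivity is the percentage of
#' "probably PIR" among true PIR, specificity the percentage of "probably AIR"
#' among true AIR, accuracy the percentage of correct calls overall.
#'
#' @param p_pir predicted probabilities of being PIR, in `[0, 1]`.
#' @param labels true labels, `"PIR"`/`"AIR"`.
#' @return list `calls` (character), `sensitivity`, `specificity`, `accuracy`
#'   (all in percent), `confusion` (2x2 table).
#' @export
classify_and_tabulate <- function(p_pir, labels) {
  if (any(p_pir < 0 | p_pir > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  calls <- ifelse(p_pir >= 0.5, "probably PIR", "probably AIR")
  is_pir <- labels == "PIR"
  sens <- 100 * mean(calls[is_pir] == "probably PIR")
  spec <- 100 * mean(calls[!is_pir] == "probably AIR")
  acc <- 100 * mean((calls == "probably PIR") == is_pir)
  confusion <- table(truth = labels, call = calls)
  list(calls = calls, sensitivity = sens, specificity = spec, accuracy = acc,
       confusion = confusion)
}

#' Published three-predictor logistic models of PIR outcome
#'
#' The four published coefficient sets mapping early-timepoint covariates to
#' the probability of being a poor immunological responder,
#' `P(PIR) = 1 / (1 + exp(a + b x1 + c x2 + d x3))` (the exponent is the AIR
#' linear predictor under the `Y = 1` AIR coding). Shipped as a transcribed
#' JSON resource.
#'
#' @return list of models; each has `name`, `n`, coefficients `a`-`d` and
#'   `predictors` (ordered names with units).
#' @export
published_models <- function() {
  path <- system.file("extdata", "published_models.json",
                      package = "immunorecov", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Evaluate a published model on covariates
#'
#' @param model one element of [published_models()] (or its name/number).
#' @param covariates data.frame containing the model's predictor columns on
#'   the study units (age in years, log10 copies/mL, cells/uL, percent).
#' @return data.frame `p_pir`, `call`; patients with a missing predictor get
#'   `NA` and no call.
#' @export
evaluate_published_model <- function(model, covariates) {
  if (is.numeric(model) || is.character(model)) {
    model <- published_models()[[model]]
  }
  vars <- vapply(model$predictors, `[[`, character(1), "variable")
  missing_cols <- setdiff(vars, names(covariates))
  if (length(missing_cols)) {
    stop("covariates lack predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(covariates[, vars, drop = FALSE])
  eta <- model$a + X %*% c(model$b, model$c, model$d)
  p_pir <- as.vector(1 / (1 + exp(eta)))
  n_missing <- sum(is.na(p_pir))
  if (n_missing) {
    message(n_missing, " patient(s) with missing predictors: no prediction")
  }
  data.frame(p_pir = p_pir,
             call = ifelse(is.na(p_pir), NA_character_,
                           ifelse(p_pir >= 0.5, "probably PIR",
                                  "probably AIR")),
             stringsAsFactors = FALSE)
}

#' Early-timepoint predictor table for outcome modelling
#'
#' Assembles, per patient, the baseline-to-6-month variables used by the
#' outcome models: age, baseline log10 viral load, CD4 counts at 2 and 6
#' months, the least-squares CD4 slope over \[0, 6\] months, RTE percentage at
#' 6 months and the baseline/6-month RTE percentage ratio.
#'
#' @param cohort a `recov_cohort`.
#' @return data.frame keyed by `patient_id`.
#' @export
predictor_table <- function(cohort) {
  cov <- cohort$covariates
  at_time <- function(id, analyte, t) {
    s <- visit_series(cohort, id, analyte)
    v <- s$value[s$time_months == t]
    if (length(v)) v[1] else NA_real_
  }
  out <- data.frame(
    patient_id = cov$patient_id,
    age_years = cov$age_years,
    log10_vl_baseline = cov$log10_vl_baseline,
    stringsAsFactors = FALSE)
  out$cd4_count_2mo <- vapply(cov$patient_id, at_time, numeric(1),
                              analyte = "cd4_count", t = 2)
  out$cd4_count_6mo <- vapply(cov$patient_id, at_time, numeric(1),
                              analyte = "cd4_count", t = 6)
  out$cd4_slope_0_6 <- vapply(cov$patient_id, function(id) {
    cd4_slope(visit_series(cohort, id, "cd4_count"), 0, 6)
  }, numeric(1))
  out$rte_pct_6mo <- vapply(cov$patient_id, at_time, numeric(1),
                            analyte = "rte_pct", t = 6)
  rte0 <- vapply(cov$patient_id, at_time, numeric(1),
                 analyte = "rte_pct", t = 0)
  out$rte_ratio_0_6mo <- ifelse(!is.na(out$rte_pct_6mo) &
                                  out$rte_pct_6mo != 0,
                                rte0 / out$rte_pct_6mo, NA_real_)
  rownames(out) <- NULL
  out
}
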