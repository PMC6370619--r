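#' Kinetic model specification
#'
#' Which fixed effects of `X(t) = A + B[1 - exp(-t/tau)]` are shared across
#' patient groups and which vary by group, plus the set of patient-level
#' random effects. The study's CD4-count model is `A` shared, `B` and `tau`
#' by group, random effects on `A` and `B`; its CD4/CD8-ratio model is `A`
#' shared, `B` by group, `tau` shared, random effects on `A`, `B` and `tau`.
#'
#' @param A,B,tau `"shared"` or `"group"`.
#' @param random subset of `c("A", "B", "tau")`.
#' @return list of class `"kinetic_model_spec"`.
#' @export
kinetic_model_spec <- function(A = "shared", B = "group", tau = "group",
                               random = c("A", "B")) {
  opts <- c("shared", "group")
  if (!all(c(A, B, tau) %in% opts)) stop("effects must be 'shared' or 'group'")
  if (!all(random %in% c("A", "B", "tau")) || !length(random)) {
    stop("'random' must be a non-empty subset of A, B, tau")
  }
  structure(list(A = A, B = B, tau = tau, random = random),
            class = "kinetic_model_spec")
}

#' @rdname kinetic_model_spec
#' @export
study_cd4_spec <- function() {
  kinetic_model_spec(A = "shared", B = "group", tau = "group",
                     random = c("A", "B"))
}

#' @rdname kinetic_model_spec
#' @export
study_ratio_spec <- function() {
  kinetic_model_spec(A = "shared", B = "group", tau = "shared",
                     random = c("A", "B", "tau"))
}

resolve_spec <- function(spec) {
  if (inherits(spec, "kinetic_model_spec")) return(spec)
  switch(spec,
         "study-cd4" = study_cd4_spec(),
         "study-ratio" = study_ratio_spec(),
         stop("unknown model spec '", spec, "'"))
}

# long model frame: patient, group (factor), time, value
kinetics_model_frame <- function(cohort, labels, analyte) {
  visits <- if (inherits(cohort, "recov_cohort")) cohort$visits else cohort
  v <- visits[visits$analyte == analyte & !is.na(visits$value), ]
  if (nrow(v) == 0) stop("no '", analyte, "' measurements found")
  lab_col <- intersect(c("label", "group", "true_group"), names(labels))[1]
  if (is.na(lab_col)) stop("'labels' needs a label/group column")
  grp <- stats::setNames(labels[[lab_col]], labels$patient_id)
  unlabelled <- setdiff(unique(v$patient_id), labels$patient_id)
  if (length(unlabelled)) {
    stop("patients without a group label (run clustering first): ",
         paste(unlabelled, collapse = ", "))
  }
  df <- data.frame(patient = v$patient_id,
                   group = factor(grp[v$patient_id]),
                   time = v$time_months, value = v$value,
                   stringsAsFactors = FALSE)
  nvis <- table(df$patient)
  if (any(nvis < 3)) stop("every patient needs >= 3 visits; offending: ",
                          paste(names(nvis)[nvis < 3], collapse = ", "))
  if (length(unique(df$time)) < 3) {
    stop("degenerate design: visits concentrated on too few distinct times")
  }
  npat <- table(unique(df[c("patient", "group")])$group)
  if (any(npat < 2)) stop("every group needs >= 2 patients")
  df$patient <- factor(df$patient)
  df
}

two_stage_patient_fits <- function(df) {
  pats <- levels(df$patient)
  est <- matrix(NA_real_, length(pats), 3,
                dimnames = list(pats, c("A", "B", "tau")))
  rss <- 0; nobs <- 0
  for (p in pats) {
    d <- df[df$patient == p, ]
    a0 <- d$value[which.min(d$time)]
    b0 <- max(max(d$value) - a0, 1e-3)
    # box constraints keep weakly identified late-linear trajectories from
    # running to huge correlated (B, tau)
    b_max <- 20 * max(diff(range(d$value)), 1e-3)
    fit <- tryCatch(
      minpack.lm::nlsLM(value ~ A + B * (1 - exp(-time / tau)), data = d,
                        start = list(A = a0, B = b0, tau = 12),
                        lower = c(-Inf, 0, 0.05),
                        upper = c(Inf, b_max, 300),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est[p, ] <- stats::coef(fit)
      rss <- rss + sum(stats::resid(fit)^2)
      nobs <- nobs + nrow(d)
    }
  }
  list(est = est, sigma = sqrt(rss / max(nobs - 3 * sum(!is.na(est[, 1])), 1)))
}

# Exact-ML route for specs whose random effects sit on {A, B} only: given
# tau the model is a linear mixed model in (A_i, B_i) with basis
# f(t) = 1 - exp(-t/tau), so the marginal likelihood is profiled over the
# (log) timescales with an inner lme step.
profile_ml_fit <- function(df, spec, groups, tau0 = 12, max_iter = 200,
                           tol = 1e-6) {
  rhs <- paste(c(if (spec$A == "group") "group",
                 if (spec$B == "group") "f:group" else "f"),
               collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs))
  ran_form <- if (setequal(spec$random, c("A", "B"))) {
    stats::as.formula("~ f | patient")
  } else if (identical(spec$random, "A")) {
    stats::as.formula("~ 1 | patient")
  } else {
    stats::as.formula("~ 0 + f | patient")
  }
  inner <- function(tau, return_fit = FALSE) {
    tau_by_g <- if (spec$tau == "group") {
      stats::setNames(tau, groups)
    } else {
      stats::setNames(rep(tau, length(groups)), groups)
    }
    d <- df
    d$f <- 1 - exp(-d$time / tau_by_g[as.character(d$group)])
    fit <- try(suppressWarnings(nlme::lme(
      form, random = ran_form, data = d, method = "ML",
      control = nlme::lmeControl(opt = "optim", maxIter = max_iter,
                                 msMaxIter = max_iter,
                                 returnObject = TRUE))), silent = TRUE)
    if (inherits(fit, "try-error")) return(if (return_fit) NULL else 1e10)
    if (return_fit) fit else -as.numeric(stats::logLik(fit))
  }
  n_tau <- if (spec$tau == "group") length(groups) else 1L
  if (n_tau == 1) {
    o <- stats::optim(log(tau0), function(lt) inner(exp(lt)),
                      method = "Brent", lower = log(0.5), upper = log(300))
  } else {
    o <- stats::optim(rep(log(tau0), n_tau), function(lt) inner(exp(lt)),
                      method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = tol))
  }
  if (o$value >= 1e10) stop("inner linear mixed-effects step failed")
  tau_hat <- exp(o$par)
  fit <- inner(tau_hat, return_fit = TRUE)
  if (is.null(fit)) stop("inner linear mixed-effects step failed")
  fe <- nlme::fixef(fit)
  A <- if (spec$A == "group") {
    base <- fe[["(Intercept)"]]
    stats::setNames(base + c(0, vapply(groups[-1], function(g) {
      fe[[paste0("group", g)]]
    }, numeric(1))), groups)
  } else {
    stats::setNames(rep(fe[["(Intercept)"]], length(groups)), groups)
  }
  B <- if (spec$B == "group") {
    stats::setNames(vapply(groups, function(g) fe[[paste0("f:group", g)]],
                           numeric(1)), groups)
  } else {
    stats::setNames(rep(fe[["f"]], length(groups)), groups)
  }
  tau <- if (spec$tau == "group") stats::setNames(tau_hat, groups) else
    stats::setNames(rep(tau_hat, length(groups)), groups)
  re <- nlme::ranef(fit)
  pat_group <- df$group[match(rownames(re), df$patient)]
  patient_coefs <- data.frame(
    patient_id = rownames(re),
    A = unname(A[as.character(pat_group)]) +
      (if ("(Intercept)" %in% names(re)) re[["(Intercept)"]] else 0),
    B = unname(B[as.character(pat_group)]) +
      (if ("f" %in% names(re)) re[["f"]] else 0),
    tau = unname(tau[as.character(pat_group)]),
    row.names = NULL)
  vc <- as.matrix(nlme::pdMatrix(fit$modelStruct$reStruct[[1]])) * fit$sigma^2
  dimnames(vc) <- rep(list(ifelse(rownames(vc) == "(Intercept)", "A", "B")),
                      2)
  list(A = A, B = B, tau = tau, ranef_cov = vc, sigma = fit$sigma,
       logLik = as.numeric(stats::logLik(fit)),
       patient_coefs = patient_coefs, converged = o$convergence == 0)
}

# fixed-effect / group bookkeeping shared by both estimation routes
groupwise <- function(value_by_group, sharing, groups) {
  if (sharing == "shared") {
    stats::setNames(rep(mean(value_by_group), length(groups)), groups)
  } else {
    stats::setNames(value_by_group[groups], groups)
  }
}

#' Fit the exponential recovery nonlinear mixed-effects model
#'
#' Fits `X(t) = A + B[1 - exp(-t/tau)]` to a labelled cohort with the sharing
#' structure of `spec` by maximum marginal likelihood. When the random-effect
#' set is a subset of `{A, B}` the model is linear given `tau`, so the exact
#' marginal likelihood is maximized by alternating an outer optimization over
#' the (log) timescales with an inner linear mixed-effects step
#' ([nlme::lme()]) — this avoids the linearization bias that a first-order
#' conditional approximation incurs for this design. Specs with a random
#' `tau` (the CD4/CD8-ratio model) use the first-order conditional
#' approximation via [nlme::nlme()]. Either route falls back, on failure
#' (e.g. degenerate noise-free data with a singular marginal likelihood), to
#' a two-stage estimator: per-patient nonlinear least-squares curve fits,
#' fixed effects and random-effect covariance by moments.
#'
#' @param cohort a `recov_cohort` or long visits data.frame.
#' @param labels data.frame with `patient_id` and a `label`/`group`/
#'   `true_group` column; every patient with data must be labelled.
#' @param analyte `"cd4_count"` or `"cd4_cd8_ratio"`.
#' @param spec a [kinetic_model_spec()] or `"study-cd4"` / `"study-ratio"`.
#' @param method `"auto"` (profile or FOCE as the random-effect set allows,
#'   with fallbacks), `"profile"`, `"nlme"` (FOCE), or `"two-stage"`.
#' @param tau0 starting value for `tau` (months).
#' @param max_iter,tol optimizer iteration cap and relative tolerance.
#' @return object of class `"kinetic_fit"`: per-group `A`, `B`, `tau`,
#'   `asymptote`, random-effect covariance `ranef_cov`, residual SD `sigma`,
#'   `logLik`, per-patient `patient_coefs`, `converged`, `method`.
#' @export
fit_recovery_nlme <- function(cohort, labels, analyte = "cd4_count",
                              spec = "study-cd4", method = "auto",
                              tau0 = 12, max_iter = 200, tol = 1e-6) {
  spec <- resolve_spec(spec)
  df <- kinetics_model_frame(cohort, labels, analyte)
  groups <- levels(df$group)
  cond_linear <- all(spec$random %in% c("A", "B"))
  if (method == "profile" && !cond_linear) {
    stop("profile route needs the random-effect set within {A, B}")
  }

  # starting values from coarse data summaries
  A0 <- mean(df$value[df$time == min(df$time)])
  Bg0 <- vapply(groups, function(g) {
    d <- df[df$group == g, ]
    d$patient <- droplevels(d$patient)
    last <- tapply(d$value, d$patient, function(v) v[length(v)])
    first <- tapply(d$value, d$patient, function(v) v[1])
    max(mean(last - first), 1e-3)
  }, numeric(1))

  build_start <- function() {
    st <- if (spec$A == "shared") A0 else c(A0, rep(0, length(groups) - 1))
    st <- c(st, if (spec$B == "shared") mean(Bg0) else
      c(Bg0[1], Bg0[-1] - Bg0[1]))
    st <- c(st, if (spec$tau == "shared") tau0 else
      c(tau0, rep(0, length(groups) - 1)))
    st
  }

  term <- function(p) stats::as.formula(
    paste(p, "~", if (spec[[p]] == "group") "group" else "1"))
  fixed <- list(term("A"), term("B"), term("tau"))
  ran_formula <- stats::as.formula(
    paste(paste(spec$random, collapse = " + "), "~ 1"))

  try_nlme <- function(pd) {
    tryCatch(suppressWarnings(nlme::nlme(
      value ~ A + B * (1 - exp(-time / tau)),
      data = df, fixed = fixed,
      random = pd(ran_formula),
      groups = ~patient, start = build_start(),
      control = nlme::nlmeControl(maxIter = max_iter, msMaxIter = max_iter,
                                  tolerance = tol, returnObject = FALSE)
    )), error = function(e) NULL)
  }
  # the optimizer's compiled code is not crash-safe when a random-effect
  # variance collapses to singularity (e.g. a random tau fitted to data with
  # no patient-level tau variation), so each attempt runs in a forked child
  # and a dead child is treated as a failed attempt
  try_nlme_protected <- function(pd) {
    if (.Platform$OS.type != "unix") return(try_nlme(pd))
    job <- parallel::mcparallel(try_nlme(pd), silent = TRUE)
    res <- suppressWarnings(parallel::mccollect(job))[[1]]
    if (is.null(res) || inherits(res, "try-error")) NULL else res
  }

  if (cond_linear && method %in% c("auto", "profile")) {
    pf <- tryCatch(profile_ml_fit(df, spec, groups, tau0 = tau0,
                                  max_iter = max_iter, tol = tol),
                   error = function(e) NULL)
    # under "auto", a profile fit whose outer optimizer did not converge
    # (degenerate likelihood, e.g. noise-free data) yields to the fallbacks
    if (!is.null(pf) && !pf$converged && method == "auto") pf <- NULL
    if (!is.null(pf)) {
      out <- c(list(analyte = analyte, spec = spec, method = "profile-ml",
                    groups = groups),
               pf[c("A", "B", "tau")],
               list(asymptote = pf$A + pf$B, ranef_cov = pf$ranef_cov,
                    sigma = pf$sigma, logLik = pf$logLik,
                    patient_coefs = pf$patient_coefs,
                    converged = pf$converged,
                    n_patients = nlevels(df$patient), fit = NULL))
      class(out) <- "kinetic_fit"
      return(out)
    }
    if (method == "profile") stop("profile-ML estimation failed")
  }

  fit <- NULL
  used <- NULL
  if (method %in% c("auto", "nlme")) {
    fit <- try_nlme_protected(nlme::pdSymm)
    used <- "nlme"
    if (is.null(fit)) {
      fit <- try_nlme_protected(nlme::pdDiag)
      used <- if (!is.null(fit)) "nlme-diag" else NULL
    }
  }

  if (!is.null(fit)) {
    fe <- nlme::fixef(fit)
    fe_group <- function(p) {
      if (spec[[p]] == "shared") {
        stats::setNames(rep(unname(fe[[p]]), length(groups)), groups)
      } else {
        base <- fe[[paste0(p, ".(Intercept)")]]
        vals <- base + c(0, vapply(groups[-1], function(g) {
          unname(fe[[paste0(p, ".group", g)]])
        }, numeric(1)))
        stats::setNames(vals, groups)
      }
    }
    A <- fe_group("A"); B <- fe_group("B"); tau <- fe_group("tau")
    pc <- stats::coef(fit)
    patient_coefs <- data.frame(patient_id = rownames(pc), pc,
                                row.names = NULL, check.names = FALSE)
    out <- list(analyte = analyte, spec = spec, method = used,
                groups = groups, A = A, B = B, tau = tau,
                asymptote = A + B,
                ranef_cov = as.matrix(nlme::pdMatrix(
                  fit$modelStruct$reStruct[[1]])) * fit$sigma^2,
                sigma = fit$sigma, logLik = as.numeric(stats::logLik(fit)),
                patient_coefs = patient_coefs, converged = TRUE,
                n_patients = nlevels(df$patient), fit = fit)
    class(out) <- "kinetic_fit"
    return(out)
  }
  if (method == "nlme") {
    stop("nlme estimation failed to converge; try method = 'auto'")
  }

  # two-stage route: per-patient curve fits, then moments
  ts <- two_stage_patient_fits(df)
  est <- ts$est
  ok <- !is.na(est[, 1])
  if (sum(ok) < 2) stop("two-stage estimation failed: too few patient fits")
  pat_group <- df$group[match(rownames(est), df$patient)]
  gm <- function(p) vapply(groups, function(g) {
    mean(est[ok & pat_group == g, p])
  }, numeric(1))
  A <- groupwise(gm("A"), spec$A, groups)
  B <- groupwise(gm("B"), spec$B, groups)
  tau <- groupwise(gm("tau"), spec$tau, groups)
  dev <- est[ok, spec$random, drop = FALSE]
  # centre within group before taking moments so group effects do not inflate
  # the random-effect covariance
  for (p in colnames(dev)) {
    ctr <- stats::setNames(vapply(groups, function(g) {
      mean(est[ok & pat_group == g, p])
    }, numeric(1)), groups)
    dev[, p] <- dev[, p] - ctr[as.character(pat_group[ok])]
  }
  ranef_cov <- stats::cov(dev)
  patient_coefs <- data.frame(patient_id = rownames(est)[ok],
                              est[ok, , drop = FALSE], row.names = NULL)
  out <- list(analyte = analyte, spec = spec, method = "two-stage",
              groups = groups, A = A, B = B, tau = tau, asymptote = A + B,
              ranef_cov = ranef_cov, sigma = ts$sigma, logLik = NA_real_,
              patient_coefs = patient_coefs, converged = all(ok),
              n_patients = nlevels(df$patient), fit = NULL)
  class(out) <- "kinetic_fit"
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Exponential recovery fit (%s, %s; %d patients)\n",
              x$analyte, x$method, x$n_patients))
  for (g in x$groups) {
    cat(sprintf("  %s: X(t) = %.4g + %.4g [1 - exp(-t/%.4g)]  plateau %.4g\n",
                g, x$A[[g]], x$B[[g]], x$tau[[g]], x$asymptote[[g]]))
  }
  cat(sprintf("  residual SD %.4g; logLik %.4g; converged: %s\n",
              x$sigma, x$logLik, x$converged))
  invisible(x)
}

#' @rdname asymptote
#' @export
asymptote.kinetic_fit <- function(object, ...) object$asymptote

#' Population mean recovery curve of a fitted group
#'
#' @param fit a [fit_recovery_nlme()] result.
#' @param group group label present in the fit.
#' @param times months on ART at which to evaluate.
#' @return data.frame `time_months`, `value`.
#' @export
predict_mean_curve <- function(fit, group, times) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!group %in% fit$groups) stop("unknown group '", group, "'")
  data.frame(time_months = times,
             value = evaluate_kinetics(fit$A[[group]], fit$B[[group]],
                                       fit$tau[[group]], times))
}
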