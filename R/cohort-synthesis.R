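#' The study visit schedule
#'
#' Scheduled months on ART at which blood was drawn: baseline (0, just before
#' ART initiation) then 2, 6, 12, 16, 20, 24, 28, 32, 36, 42, 48, 54 and 60
#' months. Thymic imaging uses {0, 12}; TREC and RTE panels use
#' {0, 6, 12, 24, 36}.
#'
#' @return strictly increasing numeric vector starting at 0.
#' @export
default_visit_schedule <- function() {
  c(0, 2, 6, 12, 16, 20, 24, 28, 32, 36, 42, 48, 54, 60)
}

trec_rte_times <- function(schedule) intersect(c(0, 6, 12, 24, 36), schedule)

#' Baseline covariate generator settings
#'
#' Per-group location/spread used to draw baseline covariates and
#' thymic-function surrogates. Defaults emulate the published cohort summaries:
#' age 38.1 +/- 8.6 (AIR) vs 45.3 +/- 10.8 (PIR) years; baseline log10 viral
#' load centred at the group medians 5.96 vs 5.41 with SDs chosen so the
#' printed min-max ranges sit at about +/- 2.5 SD; male fractions 9/14 vs
#' 14/19; HCV co-infection 2/14 vs 7/19; CDC clinical categories A/B/C in the
#' printed proportions; thymic volume gain over the first year of ART
#' 6.47 +/- 4.59 (AIR) vs 1.43 +/- 4.89 cm^3 (PIR). RTE percentage follows a
#' logistic-in-time curve with a group-specific plateau; sj- and DJbeta1-TREC
#' frequencies are log-normal with a higher sj/beta ratio in AIR. These last
#' generator shapes are modelling choices, not published estimates (see the
#' package vignette).
#'
#' @param missing_prob probability that a non-baseline scheduled visit is
#'   missed (independent Bernoulli per patient-visit; the baseline visit is
#'   never removed).
#' @param link_coefficients optional named list `(intercept, age_years,
#'   log10_vl_baseline)` of logistic coefficients on the probability of being
#'   PIR. When supplied, group membership is drawn per patient from these
#'   covariates instead of using fixed group sizes.
#' @return list of class `"covariate_model"`.
#' @export
covariate_model <- function(missing_prob = 0.05, link_coefficients = NULL) {
  if (missing_prob < 0 || missing_prob > 1) {
    stop("'missing_prob' must be in [0, 1]")
  }
  structure(list(
    age = list(AIR = c(mean = 38.1, sd = 8.6),
               PIR = c(mean = 45.3, sd = 10.8),
               range = c(18, 90)),
    log10_vl = list(AIR = c(mean = 5.96, sd = (6.98 - 5.25) / 5),
                    PIR = c(mean = 5.41, sd = (6.84 - 4.78) / 5)),
    p_male = c(AIR = 9 / 14, PIR = 14 / 19),
    p_hcv = c(AIR = 2 / 14, PIR = 7 / 19),
    clinical_category = list(AIR = c(A = 1, B = 4, C = 9) / 14,
                             PIR = c(A = 2, B = 10, C = 7) / 19),
    thymic_volume_bl = c(mean = 10, sd = 5),
    thymic_volume_gain = list(AIR = c(mean = 6.47, sd = 4.59),
                              PIR = c(mean = 1.43, sd = 4.89)),
    thymic_index_probs = list(AIR = c(`1` = 0.2, `2` = 0.4, `3` = 0.4),
                              PIR = c(`1` = 0.4, `2` = 0.4, `3` = 0.2)),
    rte = list(plateau = c(AIR = 30, PIR = 18), baseline = 8,
               t_mid = 6, scale = 6, sd = 3),
    sj_trec = list(meanlog = c(AIR = log(1500), PIR = log(700)), sdlog = 0.8),
    sj_beta_ratio = list(meanlog = c(AIR = log(8), PIR = log(5)), sdlog = 0.5),
    missing_prob = missing_prob,
    link_coefficients = link_coefficients
  ), class = "covariate_model")
}

#' Configuration of a synthetic study cohort
#'
#' Defaults reproduce the study conditions: 14 AIR-like and 19 PIR-like
#' patients on the 14-visit schedule, CD4 kinetics
#' `130.1 + 499.0 [1 - exp(-t/17.6)]` (AIR) and
#' `130.1 + 284.5 [1 - exp(-t/31.9)]` (PIR), CD4/CD8 ratio kinetics
#' `0.163 + 0.644 [1 - exp(-t/27.620)]` (AIR) and
#' `0.163 + 0.475 [1 - exp(-t/27.620)]` (PIR). Patient-level dispersion and
#' measurement noise are not published; defaults are sigma_A = 60,
#' sigma_B = 120, sigma_eps = 50 cells/uL (values floored at 1) for counts and
#' sigma_A = 0.03, sigma_B = 0.08, sigma_eps = 0.05 (floored at 0.001) for the
#' ratio.
#'
#' @param n_air,n_pir group sizes (ignored for membership when the covariate
#'   model carries `link_coefficients`; the total is kept).
#' @param schedule visit schedule, see [default_visit_schedule()].
#' @param cd4,ratio named lists `list(AIR = , PIR = )` of [group_kinetics()].
#' @param covariates a [covariate_model()].
#' @param seed default seed used by [generate_cohort()].
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_air = 14, n_pir = 19,
                          schedule = default_visit_schedule(),
                          cd4 = list(
                            AIR = group_kinetics(130.1, 499.0, 17.6,
                                                 sigma_A = 60, sigma_B = 120,
                                                 sigma_eps = 50, floor = 1),
                            PIR = group_kinetics(130.1, 284.5, 31.9,
                                                 sigma_A = 60, sigma_B = 120,
                                                 sigma_eps = 50, floor = 1)),
                          ratio = list(
                            AIR = group_kinetics(0.163, 0.644, 27.620,
                                                 sigma_A = 0.03, sigma_B = 0.08,
                                                 sigma_eps = 0.05,
                                                 floor = 0.001),
                            PIR = group_kinetics(0.163, 0.475, 27.620,
                                                 sigma_A = 0.03, sigma_B = 0.08,
                                                 sigma_eps = 0.05,
                                                 floor = 0.001)),
                          covariates = covariate_model(),
                          seed = 1L) {
  if (n_air < 1 || n_pir < 1) stop("group sizes must be >= 1")
  if (length(schedule) == 0) stop("empty visit schedule")
  if (schedule[1] != 0 || is.unsorted(schedule, strictly = TRUE)) {
    stop("schedule must be strictly increasing and start at 0 (baseline)")
  }
  for (kin in c(cd4, ratio)) {
    if (!inherits(kin, "group_kinetics")) {
      stop("'cd4' and 'ratio' must be lists of group_kinetics (AIR, PIR)")
    }
  }
  structure(list(n_air = n_air, n_pir = n_pir, schedule = schedule,
                 cd4 = cd4, ratio = ratio, covariates = covariates,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate one patient's visit series under the recovery model
#'
#' Draws patient-level parameters `A_i ~ N(A, sigma_A^2)`,
#' `B_i ~ N(B, sigma_B^2)` and returns
#' `A_i + B_i (1 - exp(-t/tau)) + eps_t` at each scheduled time, with
#' `eps_t ~ N(0, sigma_eps^2)` and values floored at `kin$floor`. Uses the
#' current RNG stream; with all SDs zero the series equals the deterministic
#' mean curve.
#'
#' @param kin a [group_kinetics()] object.
#' @param schedule visit times (months), strictly increasing from 0.
#' @return data.frame with columns `time_months`, `value`.
#' @export
generate_trajectory <- function(kin, schedule = default_visit_schedule()) {
  if (!inherits(kin, "group_kinetics")) stop("'kin' must be a group_kinetics")
  if (length(schedule) == 0) stop("empty visit schedule")
  A_i <- kin$A + stats::rnorm(1, 0, kin$sigma_A)
  B_i <- max(kin$B + stats::rnorm(1, 0, kin$sigma_B), 0)
  eps <- stats::rnorm(length(schedule), 0, kin$sigma_eps)
  value <- pmax(A_i + B_i * (1 - exp(-schedule / kin$tau)) + eps, kin$floor)
  data.frame(time_months = schedule, value = value)
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a seeded synthetic cohort
#'
#' Produces per-patient CD4 count, CD8 count and CD4/CD8 ratio series on the
#' full schedule, RTE percentages and sj-/DJbeta1-TREC frequencies at the
#' assay visits, baseline covariates, thymic imaging variables and the true
#' group labels. Visit-level missingness (never at baseline) is applied last.
#' Identical `(config, seed)` give identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return object of class `"recov_cohort"`: list with `visits` (long format:
#'   `patient_id`, `time_months`, `analyte`, `value`), `covariates` (one row
#'   per patient, includes `true_group`), `schedule`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  n <- config$n_air + config$n_pir
  if (n < 1) stop("zero patients requested")
  cm <- config$covariates
  ids <- sprintf("P%02d", seq_len(n))

  if (is.null(cm$link_coefficients)) {
    group <- rep(c("AIR", "PIR"), c(config$n_air, config$n_pir))
    age <- vl <- numeric(n)
    for (g in c("AIR", "PIR")) {
      idx <- group == g
      age[idx] <- rtrunc_norm(sum(idx), cm$age[[g]]["mean"], cm$age[[g]]["sd"],
                              cm$age$range[1], cm$age$range[2])
      vl[idx] <- stats::rnorm(sum(idx), cm$log10_vl[[g]]["mean"],
                              cm$log10_vl[[g]]["sd"])
    }
  } else {
    # covariate-driven membership: draw age/VL from the pooled mixture, then
    # the group from the logistic link on (age, log10 VL)
    age <- rtrunc_norm(n, 42.2, 10.4, cm$age$range[1], cm$age$range[2])
    vl <- stats::rnorm(n, 5.6, 0.5)
    lc <- cm$link_coefficients
    eta <- lc$intercept + lc$age_years * age + lc$log10_vl_baseline * vl
    group <- ifelse(stats::runif(n) < stats::plogis(eta), "PIR", "AIR")
    if (length(unique(group)) == 1L) {      # guarantee both groups present
      group[sample.int(n, 1)] <- setdiff(c("AIR", "PIR"), group[1])
    }
  }

  sex <- ifelse(stats::runif(n) < cm$p_male[group], "male", "female")
  hcv <- as.integer(stats::runif(n) < cm$p_hcv[group])
  ccat <- vapply(group, function(g) {
    sample(names(cm$clinical_category[[g]]), 1,
           prob = cm$clinical_category[[g]])
  }, character(1))
  tvol0 <- rtrunc_norm(n, cm$thymic_volume_bl["mean"],
                       cm$thymic_volume_bl["sd"], 0.5, 40)
  tgain <- numeric(n)
  for (g in c("AIR", "PIR")) {
    idx <- group == g
    tgain[idx] <- stats::rnorm(sum(idx), cm$thymic_volume_gain[[g]]["mean"],
                               cm$thymic_volume_gain[[g]]["sd"])
  }
  tvol12 <- pmax(tvol0 + tgain, 0.5)
  tidx0 <- vapply(group, function(g) {
    as.integer(sample(names(cm$thymic_index_probs[[g]]), 1,
                      prob = cm$thymic_index_probs[[g]]))
  }, integer(1))
  tidx12 <- pmin(tidx0 + stats::rbinom(n, 1, 0.3), 5L)

  covariates <- data.frame(
    patient_id = ids, age_years = age, log10_vl_baseline = vl, sex = sex,
    clinical_category = ccat, hcv = hcv,
    thymic_volume_bl = tvol0, thymic_volume_12 = tvol12,
    thymic_index_bl = tidx0, thymic_index_12 = tidx12,
    true_group = group, stringsAsFactors = FALSE, row.names = NULL
  )

  sched <- config$schedule
  assay_t <- trec_rte_times(sched)
  visits <- vector("list", n)
  for (i in seq_len(n)) {
    g <- group[i]
    cd4 <- generate_trajectory(config$cd4[[g]], sched)
    rat <- generate_trajectory(config$ratio[[g]], sched)
    cd8 <- cd4$value / rat$value
    rte_mu <- cm$rte$baseline +
      cm$rte$plateau[[g]] / (1 + exp(-(assay_t - cm$rte$t_mid) / cm$rte$scale))
    rte <- pmin(pmax(rte_mu + stats::rnorm(length(assay_t), 0, cm$rte$sd), 0),
                100)
    sj <- stats::rlnorm(length(assay_t), cm$sj_trec$meanlog[[g]],
                        cm$sj_trec$sdlog)
    dj <- sj / stats::rlnorm(length(assay_t), cm$sj_beta_ratio$meanlog[[g]],
                             cm$sj_beta_ratio$sdlog)
    pat <- rbind(
      data.frame(time_months = sched, analyte = "cd4_count",
                 value = cd4$value),
      data.frame(time_months = sched, analyte = "cd8_count", value = cd8),
      data.frame(time_months = sched, analyte = "cd4_cd8_ratio",
                 value = rat$value),
      data.frame(time_months = assay_t, analyte = "rte_pct", value = rte),
      data.frame(time_months = assay_t, analyte = "sj_trec_per1e5",
                 value = sj),
      data.frame(time_months = assay_t, analyte = "dj_trec_per1e5",
                 value = dj)
    )
    # visit-level missingness: a missed visit loses every analyte drawn there
    miss <- sched[-1][stats::runif(length(sched) - 1) < cm$missing_prob]
    pat <- pat[!pat$time_months %in% miss, ]
    pat$patient_id <- ids[i]
    visits[[i]] <- pat
  }
  visits <- do.call(rbind, visits)
  visits <- visits[, c("patient_id", "time_months", "analyte", "value")]
  rownames(visits) <- NULL

  structure(list(visits = visits, covariates = covariates, schedule = sched,
                 config = config, seed = as.integer(seed)),
            class = "recov_cohort")
}

#' @export
print.recov_cohort <- function(x, ...) {
  tab <- table(x$covariates$true_group)
  cat(sprintf("Synthetic ART cohort: %d patients (%s), %d visit records\n",
              nrow(x$covariates),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              nrow(x$visits)))
  cat("  schedule (months):", paste(x$schedule, collapse = " "), "\n")
  cat("  analytes:", paste(sort(unique(x$visits$analyte)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Extract one patient's series for one analyte
#'
#' @param cohort a `recov_cohort` or a long visits data.frame.
#' @param patient_id patient identifier.
#' @param analyte analyte name (e.g. `"cd4_count"`).
#' @param window optional `c(min, max)` months filter (closed interval).
#' @return data.frame `time_months`, `value`, ordered by time.
#' @export
visit_series <- function(cohort, patient_id, analyte = "cd4_count",
                         window = NULL) {
  visits <- if (inherits(cohort, "recov_cohort")) cohort$visits else cohort
  s <- visits[visits$patient_id == patient_id & visits$analyte == analyte,
              c("time_months", "value")]
  if (!is.null(window)) {
    s <- s[s$time_months >= window[1] & s$time_months <= window[2], ]
  }
  s <- s[order(s$time_months), ]
  rownames(s) <- NULL
  s
}

#' Write / read a cohort as long-format CSV
#'
#' `write_cohort()` writes `visits.csv` (`patient_id,time_months,analyte,value`)
#' and `covariates.csv` (wide, one row per patient) into `dir`; values are
#' written with full precision so the round trip is exact. `read_cohort()`
#' validates headers, numeric cells and key uniqueness, and fails naming the
#' offending row/key.
#'
#' @param cohort a `recov_cohort` (or any list with `visits` and `covariates`).
#' @param dir directory to write to / read from (created if needed).
#' @return `read_cohort()` returns a `recov_cohort` (without a generating
#'   config); `write_cohort()` returns `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- cohort$visits
  v$value <- sprintf("%.17g", v$value)
  utils::write.csv(v, file.path(dir, "visits.csv"), row.names = FALSE,
                   quote = FALSE)
  cov <- cohort$covariates
  if (!is.null(cov)) {
    for (cc in names(cov)) {
      if (is.double(cov[[cc]])) cov[[cc]] <- sprintf("%.17g", cov[[cc]])
    }
    utils::write.csv(cov, file.path(dir, "covariates.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  vpath <- file.path(dir, "visits.csv")
  if (!file.exists(vpath)) stop("no visits.csv in ", dir)
  visits <- utils::read.csv(vpath, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "analyte", "value")
  if (!identical(names(visits)[seq_along(need)], need)) {
    stop("malformed visits header: expected columns ",
         paste(need, collapse = ","))
  }
  for (cc in c("time_months", "value")) {
    raw <- visits[[cc]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & raw != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' in visits.csv at row %d: '%s'",
                   cc, bad[1], raw[bad[1]]))
    }
    visits[[cc]] <- num
  }
  key <- paste(visits$patient_id, visits$time_months, visits$analyte,
               sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (patient, time, analyte) rows in visits.csv: ",
         key[duplicated(key)][1])
  }
  cpath <- file.path(dir, "covariates.csv")
  covariates <- if (file.exists(cpath)) {
    utils::read.csv(cpath, stringsAsFactors = FALSE)
  } else NULL
  sched <- sort(unique(visits$time_months))
  structure(list(visits = visits, covariates = covariates, schedule = sched,
                 config = NULL, seed = NA_integer_),
            class = "recov_cohort")
}
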