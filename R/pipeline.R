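#' Derive a stage seed from the master seed
#'
#' Every randomized pipeline stage consumes its own sub-seed, a deterministic
#' hash of the master seed and the stage name, so stages are reproducible in
#' isolation and the full run is reproducible end to end. Kept below 2^31.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 131) %% 2147483647L)
}

#' Validate visit and covariate tables
#'
#' Returns a table of issues instead of failing: negative counts and duplicate
#' (patient, time, analyte) keys are errors; visit times off the standard
#' schedule and unknown analyte names are warnings.
#'
#' @param visits long-format visits data.frame.
#' @param covariates optional covariate data.frame.
#' @param schedule reference schedule for the off-schedule check.
#' @return data.frame `severity` (`"error"`/`"warning"`), `message`; zero rows
#'   when clean.
#' @export
validate_inputs <- function(visits, covariates = NULL,
                            schedule = default_visit_schedule()) {
  issues <- list()
  add <- function(severity, message) {
    issues[[length(issues) + 1]] <<- data.frame(severity = severity,
                                                message = message,
                                                stringsAsFactors = FALSE)
  }
  known <- c("cd4_count", "cd8_count", "cd4_cd8_ratio", "rte_pct",
             "sj_trec_per1e5", "dj_trec_per1e5", "naive_count",
             "memory_count", "pbmc_per_ml")
  counts <- visits$analyte %in% c("cd4_count", "cd8_count")
  neg <- counts & !is.na(visits$value) & visits$value < 0
  if (any(neg)) {
    add("error", sprintf("negative cell count at row %d (%s, t=%g)",
                         which(neg)[1], visits$patient_id[which(neg)[1]],
                         visits$time_months[which(neg)[1]]))
  }
  key <- paste(visits$patient_id, visits$time_months, visits$analyte,
               sep = "|")
  if (anyDuplicated(key)) {
    add("error", paste("duplicate (patient, time, analyte) key:",
                       key[duplicated(key)][1]))
  }
  off <- setdiff(unique(visits$time_months), schedule)
  if (length(off)) {
    add("warning", paste("visit times off the standard schedule:",
                         paste(sort(off), collapse = ", ")))
  }
  unknown <- setdiff(unique(visits$analyte), known)
  if (length(unknown)) {
    add("warning", paste("unknown analyte(s):",
                         paste(unknown, collapse = ", ")))
  }
  if (!is.null(covariates) && anyDuplicated(covariates$patient_id)) {
    add("error", "duplicate patient_id in covariates")
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), message = character(0))
}

compare_stage <- function(cohort, labels, alpha = 0.05) {
  cov <- merge(cohort$covariates, labels[, c("patient_id", "label")],
               by = "patient_id")
  a <- function(col) cov[[col]][cov$label == "AIR"]
  p <- function(col) cov[[col]][cov$label == "PIR"]
  numeric_feature <- function(col) {
    routed <- route_test(a(col), p(col))
    analysis <- if (routed == "t-test") independent_t else mann_whitney
    sens <- extreme_outlier_sensitivity(analysis, a(col), p(col), alpha)
    res <- sens$with_outliers
    list(feature = col, test = res$test, statistic = res$statistic,
         p = res$p, effect = res$effect, effect_kind = res$effect_kind,
         magnitude = res$magnitude,
         outlier_agreement = sens$agree,
         n_outliers_removed = sum(sens$n_removed))
  }
  categorical_feature <- function(col) {
    tab <- table(cov$label, cov[[col]])
    if (ncol(tab) == 2) {
      res <- fisher_exact_2x2(tab)
      list(feature = col, test = res$test, statistic = NA_real_, p = res$p,
           effect = res$effect, effect_kind = res$effect_kind,
           magnitude = res$magnitude, outlier_agreement = NA,
           n_outliers_removed = 0L)
    } else {
      pv <- stats::fisher.test(tab, workspace = 2e6)$p.value
      v <- cramers_v(tab)
      list(feature = col, test = "fisher-exact", statistic = NA_real_, p = pv,
           effect = v, effect_kind = "cramers_v",
           magnitude = magnitude_label("cramers_v", v),
           outlier_agreement = NA, n_outliers_removed = 0L)
    }
  }
  baseline <- c(lapply(c("age_years", "log10_vl_baseline"), numeric_feature),
                lapply(c("sex", "hcv", "clinical_category"),
                       categorical_feature))

  # per-timepoint CD4 comparisons across the schedule, Bonferroni over the
  # family of scheduled visits
  sched <- cohort$schedule
  per_time <- lapply(sched, function(t) {
    v <- cohort$visits
    at <- v[v$analyte == "cd4_count" & v$time_months == t, ]
    at <- merge(at, labels[, c("patient_id", "label")], by = "patient_id")
    if (min(table(at$label)) < 1) return(NULL)
    res <- mann_whitney(at$value[at$label == "AIR"],
                        at$value[at$label == "PIR"])
    list(time_months = t, U = res$statistic, p = res$p, r = res$effect)
  })
  per_time <- per_time[!vapply(per_time, is.null, logical(1))]
  bf <- bonferroni_flags(vapply(per_time, `[[`, numeric(1), "p"),
                         alpha = alpha, m = length(sched))
  for (i in seq_along(per_time)) {
    per_time[[i]]$significant_bonferroni <- unname(bf$flags[i])
  }
  list(baseline = baseline, cd4_by_time = per_time,
       bonferroni_threshold = bf$threshold,
       conventions = list(odds_ratio = "cross-product (a*d)/(b*c)",
                          quartiles = "linear interpolation (type 7)",
                          t_test = "pooled variance",
                          rank_r = "Z/sqrt(N), signed by first sample"))
}

predict_stage <- function(cohort, labels, screen_threshold = 0.20,
                          p_remove = 0.05) {
  pred <- predictor_table(cohort)
  pred <- merge(pred, labels[, c("patient_id", "label")], by = "patient_id")
  pred$y_air <- as.integer(pred$label == "AIR")
  candidates <- c("age_years", "log10_vl_baseline", "cd4_count_2mo",
                  "cd4_count_6mo", "cd4_slope_0_6", "rte_pct_6mo",
                  "rte_ratio_0_6mo")
  screen <- suppressWarnings(
    univariable_screen(pred, "y_air", candidates, screen_threshold))
  retained <- screen$candidate[screen$retained]
  if (!length(retained)) retained <- screen$candidate[which.min(screen$p)]
  cc <- stats::complete.cases(pred[, c("y_air", retained), drop = FALSE])
  d <- pred[cc, , drop = FALSE]
  final <- backward_stepwise(d, "y_air", retained, p_remove)
  full <- fit_logistic(d, "y_air", retained)
  lrt <- likelihood_ratio_test(final, full)
  p_air <- stats::fitted(final$glm)
  p_pir <- 1 - p_air
  truth <- d$label[match(final$rows, rownames(d))]
  roc <- roc_auc(p_pir, as.integer(truth == "PIR"))
  hl <- tryCatch(hosmer_lemeshow(p_air, d$y_air[match(final$rows,
                                                      rownames(d))]),
                 error = function(e) list(statistic = NA_real_,
                                          df = NA_real_, p = NA_real_))
  rates <- classify_and_tabulate(p_pir, truth)
  published <- lapply(published_models(), function(m) {
    vars <- vapply(m$predictors, `[[`, character(1), "variable")
    if (!all(vars %in% names(pred))) return(NULL)
    ev <- evaluate_published_model(m, pred)
    ok <- !is.na(ev$p_pir)
    acc <- if (any(ok)) {
      100 * mean((ev$p_pir[ok] >= 0.5) == (pred$label[ok] == "PIR"))
    } else NA_real_
    list(name = m$name, n_evaluated = sum(ok), accuracy = acc)
  })
  list(screen = screen, retained = retained,
       final_predictors = final$predictors,
       removal_trace = final$removal_trace,
       coefficients = as.data.frame(final$coefficients),
       lrt = lrt, auc = roc$auc, auc_label = roc$label,
       hosmer_lemeshow = hl[c("statistic", "df", "p")],
       sensitivity = rates$sensitivity, specificity = rates$specificity,
       accuracy = rates$accuracy, n = final$n,
       published = published[!vapply(published, is.null, logical(1))])
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> validate -> cluster -> kinetics -> compare ->
#' predict -> report. Every randomized stage consumes a sub-seed derived from
#' the master seed; identical `(config, seed)` produce byte-identical report
#' JSON. When the cohort has no covariates the compare and predict stages are
#' skipped with a notice in the report.
#'
#' @param config a [cohort_config()] (a cohort is simulated from it), or an
#'   existing `recov_cohort`.
#' @param seed master seed.
#' @param out_dir optional directory; when given, `report.json`,
#'   `report.md`, `assignments.csv` and `fit_cd4.json` are written there.
#' @return the report list, invisibly with class `"recov_report"`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         out_dir = NULL) {
  stage <- "simulate"
  report <- list(schema_version = "1.0", master_seed = as.integer(seed),
                 stage_seeds = list())
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- run_stage("simulate", {
    if (inherits(config, "recov_cohort")) config else {
      s <- stage_seed(seed, "simulate")
      report$stage_seeds$simulate <- s
      generate_cohort(config, seed = s)
    }
  })
  issues <- run_stage("validate", validate_inputs(cohort$visits,
                                                  cohort$covariates,
                                                  cohort$schedule))
  if (any(issues$severity == "error")) {
    stop("pipeline stage 'validate' failed: ",
         issues$message[issues$severity == "error"][1], call. = FALSE)
  }
  report$validation <- issues

  labels <- run_stage("cluster", {
    s <- stage_seed(seed, "cluster")
    report$stage_seeds$cluster <- s
    cluster_cohort(cohort, seed = s)
  })
  sel <- attr(labels, "selection")
  report$cluster <- list(
    n = nrow(labels),
    sizes = as.list(table(labels$label)),
    n_crossed_500 = sum(labels$crossed_500),
    selected_measures = sel$selected,
    eigenvalues_retained = sel$eigenvalues[seq_len(sel$n_factors)])

  fits <- run_stage("kinetics", {
    list(cd4 = fit_recovery_nlme(cohort, labels, "cd4_count", "study-cd4"),
         ratio = fit_recovery_nlme(cohort, labels, "cd4_cd8_ratio",
                                   "study-ratio"))
  })
  report$kinetics <- lapply(fits, function(f) {
    list(method = f$method, A = as.list(f$A), B = as.list(f$B),
         tau = as.list(f$tau), asymptote = as.list(f$asymptote),
         sigma = f$sigma, logLik = f$logLik, converged = f$converged)
  })

  if (is.null(cohort$covariates)) {
    report$compare <- list(skipped = "no covariates supplied")
    report$predict <- list(skipped = "no covariates supplied")
  } else {
    report$compare <- run_stage("compare", compare_stage(cohort, labels))
    report$predict <- run_stage("predict", {
      set.seed(stage_seed(seed, "predict"))
      predict_stage(cohort, labels)
    })
  }

  if (!is.null(out_dir)) {
    run_stage("report", {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = 10, pretty = TRUE,
                           na = "null")
      utils::write.csv(labels[, c("patient_id", "cluster", "label",
                                  "crossed_500")],
                       file.path(out_dir, "assignments.csv"),
                       row.names = FALSE)
      writeLines(report_markdown(report), file.path(out_dir, "report.md"))
    })
  }
  class(report) <- "recov_report"
  invisible(report)
}

report_markdown <- function(report) {
  k <- report$kinetics
  lines <- c(
    "# Immune recovery pipeline report",
    "",
    sprintf("- master seed: %d", report$master_seed),
    sprintf("- clusters: %s (patients crossing 500 cells/uL: %d)",
            paste(sprintf("%s n=%s", names(report$cluster$sizes),
                          unlist(report$cluster$sizes)), collapse = ", "),
            report$cluster$n_crossed_500),
    sprintf("- selected trajectory measures: %s",
            paste(report$cluster$selected_measures, collapse = ", ")),
    "")
  for (an in names(k)) {
    lines <- c(lines, sprintf(
      "- %s plateaus: %s", an,
      paste(sprintf("%s %.1f", names(k[[an]]$asymptote),
                    unlist(k[[an]]$asymptote)), collapse = ", ")))
  }
  if (!is.null(report$predict$auc)) {
    lines <- c(lines, sprintf(
      "- outcome model: %s; AUC %.3f (%s), accuracy %.1f%%",
      paste(report$predict$final_predictors, collapse = " + "),
      report$predict$auc, report$predict$auc_label,
      report$predict$accuracy))
  }
  lines
}

#' @export
print.recov_report <- function(x, ...) {
  cat(paste(report_markdown(x), collapse = "\n"), "\n")
  invisible(x)
}
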