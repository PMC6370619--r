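#' Route a two-group comparison to a parametric or rank test
#'
#' Shapiro-Wilk normality on each sample decides the test: both p >= 0.05 ->
#' pooled-variance t-test, otherwise Mann-Whitney. Samples of fewer than 3
#' values cannot be tested for normality and route to the nonparametric test
#' with a warning. The same logic routes correlations to Pearson vs Spearman.
#'
#' @param a,b numeric samples.
#' @param alpha normality significance level (0.05).
#' @param for_correlation if TRUE return `"pearson"`/`"spearman"` instead of
#'   `"t-test"`/`"mann-whitney"`.
#' @return character scalar naming the routed test.
#' @export
route_test <- function(a, b, alpha = 0.05, for_correlation = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  par_name <- if (for_correlation) "pearson" else "t-test"
  npar_name <- if (for_correlation) "spearman" else "mann-whitney"
  if (length(a) < 3 || length(b) < 3) {
    warning("sample(s) with n < 3: routing to the nonparametric test")
    return(npar_name)
  }
  swp <- function(x) {
    if (length(unique(x)) == 1) return(0)       # degenerate: not normal
    stats::shapiro.test(x)$p.value
  }
  if (swp(a) >= alpha && swp(b) >= alpha) par_name else npar_name
}

#' Pooled-SD Cohen's d from group summaries
#'
#' `d = |mean_a - mean_b| / s_p` with
#' `s_p = sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2))`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @return Cohen's d (non-negative).
#' @export
cohens_d_pooled <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("need n >= 2 per group")
  if (sd_a < 0 || sd_b < 0) stop("SDs must be >= 0")
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (sp == 0) stop("zero pooled SD: Cohen's d undefined")
  abs(mean_a - mean_b) / sp
}

#' Paired Cohen's d
#'
#' For within-group comparisons between two time points:
#' `d = |mean(diff)| / SD(diff)`.
#'
#' @param differences paired differences.
#' @return Cohen's d.
#' @export
paired_d <- function(differences) {
  differences <- differences[!is.na(differences)]
  if (length(differences) < 2) stop("need >= 2 paired differences")
  s <- stats::sd(differences)
  if (s == 0) stop("zero SD of differences: paired d undefined")
  abs(mean(differences)) / s
}

#' Pooled-variance independent t-test with Cohen's d
#'
#' Student's t with `df = n_a + n_b - 2` (pooled variance, matching printed
#' dfs of the form t(31) for 14 vs 19), two-sided p, and pooled-SD Cohen's d
#' as effect size.
#'
#' @param a,b numeric samples.
#' @return list of class `"test_result"`: `test`, `statistic`, `df`, `p`,
#'   `effect` (value), `effect_kind` (`"cohens_d"`), `magnitude`.
#' @export
independent_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  d <- cohens_d_pooled(mean(a), stats::sd(a), length(a),
                       mean(b), stats::sd(b), length(b))
  test_result("t-test", unname(ht$statistic), unname(ht$parameter),
              ht$p.value, d, "cohens_d")
}

#' Mann-Whitney U test with signed effect size r
#'
#' `U` counts pairs won by the first sample (ties count one half). The
#' two-sided p is exact (from the null U distribution) for tie-free samples
#' with at most 50 values each, and otherwise uses the normal approximation
#' with tie-corrected variance. The effect size is `r = Z / sqrt(n_a + n_b)`,
#' signed positive when the first sample is stochastically larger.
#'
#' @param a,b numeric samples.
#' @return `"test_result"` list; `statistic` is `U` for the first sample,
#'   `effect_kind` is `"rank_r"`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a < 1 || n_b < 1) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  n <- n_a + n_b
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  mu <- n_a * n_b / 2
  sig2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
  if (!has_ties && n_a <= 50 && n_b <= 50) {
    p <- if (U > mu) {
      2 * stats::pwilcox(U - 1, n_a, n_b, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n_a, n_b)
    }
    p <- min(p, 1)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  test_result("mann-whitney", unname(U), NA_real_, p, z / sqrt(n), "rank_r")
}

#' Fisher exact test on a 2x2 table with the cross-product odds ratio
#'
#' Two-sided p sums the hypergeometric probabilities (margins fixed) of all
#' tables no more probable than the observed one. The effect size is the
#' sample cross-product odds ratio `(a d)/(b c)` of the table as entered —
#' the convention that reproduces published cohort ORs — reported as 0 or
#' `Inf` when a single off-/on-diagonal cell is zero.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = groups, columns = outcome levels).
#' @return `"test_result"` list; `effect_kind` `"odds_ratio"`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  obs <- stats::dhyper(tab[1, 1], m, n2, k)
  p <- min(sum(probs[probs <= obs * (1 + 1e-7)]), 1)
  or <- if (tab[1, 2] * tab[2, 1] == 0) {
    if (tab[1, 1] * tab[2, 2] == 0) NaN else Inf
  } else {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  test_result("fisher-exact", NA_real_, NA_real_, p, or, "odds_ratio")
}

#' Cramer's V for an r x c contingency table
#'
#' `V = sqrt(chi^2 / (n (min(r, c) - 1)))`, in `[0, 1]`, from the Pearson
#' chi-square statistic (no continuity correction).
#'
#' @param tab contingency table (matrix of non-negative counts).
#' @return numeric scalar.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (min(dim(tab)) < 2) stop("degenerate table: need >= 2 rows and columns")
  n <- sum(tab)
  if (n <= 0) stop("empty table")
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) {
    keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
    tab <- tab[keep_r, keep_c, drop = FALSE]
    if (min(dim(tab)) < 2) stop("degenerate table after dropping empty margins")
    expected <- outer(rowSums(tab), colSums(tab)) / n
  }
  chisq <- sum((tab - expected)^2 / expected)
  sqrt(chisq / (n * (min(dim(tab)) - 1)))
}

#' Verbal magnitude of an effect size
#'
#' Bins (on the absolute value): Cohen's d — small < 0.3, medium \[0.3, 0.8),
#' large >= 0.8; rank r — small < 0.3, medium \[0.3, 0.5), large >= 0.5;
#' Cramer's V — small < 0.3, medium \[0.3, 0.7\], large > 0.7; correlation —
#' negligible < 0.3, low \[0.3, 0.5), moderate \[0.5, 0.7), high \[0.7, 0.9),
#' very high >= 0.9. Where printed bin edges overlap, the upper bin wins.
#'
#' @param kind one of `"cohens_d"`, `"rank_r"`, `"cramers_v"`,
#'   `"correlation"`, `"odds_ratio"` (no verbal scale; returns `NA`).
#' @param value effect-size value (sign ignored).
#' @return character scalar.
#' @export
magnitude_label <- function(kind, value) {
  v <- abs(value)
  switch(kind,
    cohens_d = if (v < 0.3) "small" else if (v < 0.8) "medium" else "large",
    rank_r = if (v < 0.3) "small" else if (v < 0.5) "medium" else "large",
    cramers_v = if (v < 0.3) "small" else if (v <= 0.7) "medium" else "large",
    correlation = if (v < 0.3) "negligible" else if (v < 0.5) "low" else
      if (v < 0.7) "moderate" else if (v < 0.9) "high" else "very high",
    odds_ratio = NA_character_,
    stop("unknown effect-size kind '", kind, "'"))
}

test_result <- function(test, statistic, df, p, effect, effect_kind) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 effect = effect, effect_kind = effect_kind,
                 magnitude = magnitude_label(effect_kind, effect)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %.4g; %s = %.3g (%s)\n", x$test,
              if (is.na(x$statistic)) "-" else format(x$statistic, digits = 4),
              x$p, x$effect_kind, x$effect,
              if (is.na(x$magnitude)) "-" else x$magnitude))
  invisible(x)
}

#' Bonferroni significance threshold and flags
#'
#' Threshold `alpha / m`; a p-value is flagged significant when strictly below
#' it (e.g. alpha 0.05 over 14 comparisons -> 0.004 to 3 decimals).
#'
#' @param p vector of p-values.
#' @param alpha family-wise level, default 0.05.
#' @param m number of comparisons.
#' @return list `threshold`, `flags` (logical vector).
#' @export
bonferroni_flags <- function(p, alpha = 0.05, m) {
  if (m < 1) stop("'m' must be >= 1")
  threshold <- alpha / m
  list(threshold = threshold, flags = p < threshold)
}

#' Extreme-outlier fence
#'
#' Values below `P25 - 3 IQR` or above `P75 + 3 IQR` are extreme outliers.
#' Quartiles use linear interpolation (R's default, `quantile type 7`); the
#' convention is recorded in the result.
#'
#' @param x numeric sample.
#' @return list `lower`, `upper`, `is_extreme` (logical vector),
#'   `quartile_type`.
#' @export
extreme_outlier_fence <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2] - q[1]
  lower <- unname(q[1] - 3 * iqr)
  upper <- unname(q[2] + 3 * iqr)
  list(lower = lower, upper = upper,
       is_extreme = !is.na(x) & (x < lower | x > upper),
       quartile_type = "linear interpolation (type 7)")
}

#' Run a two-sample analysis with and without extreme outliers
#'
#' Applies `analysis(a, b)` to the full samples and to the samples with
#' extreme outliers (per-sample fences) removed, and reports whether the
#' significance direction at `alpha` agrees.
#'
#' @param analysis function of two samples returning a `test_result` (or any
#'   list with a `p` element).
#' @param a,b numeric samples.
#' @param alpha significance level used for the agreement flag.
#' @return list `with_outliers`, `without_outliers`, `agree`,
#'   `n_removed` (per sample), `fences`.
#' @export
extreme_outlier_sensitivity <- function(analysis, a, b, alpha = 0.05) {
  fa <- extreme_outlier_fence(a); fb <- extreme_outlier_fence(b)
  a2 <- a[!fa$is_extreme]; b2 <- b[!fb$is_extreme]
  if (length(a2) == 0 || length(b2) == 0) {
    stop("all points of one sample flagged as extreme outliers")
  }
  full <- analysis(a, b)
  trimmed <- analysis(a2, b2)
  list(with_outliers = full, without_outliers = trimmed,
       agree = (full$p < alpha) == (trimmed$p < alpha),
       n_removed = c(a = sum(fa$is_extreme), b = sum(fb$is_extreme)),
       fences = list(a = fa, b = fb))
}

#' Per-patient CD4 slope over an ART interval
#'
#' Ordinary least-squares slope of CD4 count on time using every available
#' visit in the closed interval `[t_i, t_f]`, in cells/uL/month. Fewer than 2
#' visits in the interval yields `NA`.
#'
#' @param series data.frame `time_months`, `value`.
#' @param t_i,t_f interval bounds in months (inclusive).
#' @return numeric scalar (or `NA`).
#' @export
cd4_slope <- function(series, t_i, t_f) {
  s <- series[series$time_months >= t_i & series$time_months <= t_f &
                !is.na(series$value), ]
  if (nrow(s) < 2) return(NA_real_)
  unname(stats::lm.fit(cbind(1, s$time_months), s$value)$coefficients[2])
}

#' Thymic score
#'
#' Product of the mean thymic volume and the mean thymic index over the first
#' year of ART (typically the baseline and 12-month CT measurements).
#'
#' @param volumes thymic volumes (cm^3), one per imaging time point.
#' @param indices thymic indices (ordinal 0-5).
#' @return numeric scalar.
#' @export
thymic_score <- function(volumes, indices) {
  volumes <- volumes[!is.na(volumes)]; indices <- indices[!is.na(indices)]
  if (!length(volumes) || !length(indices)) {
    stop("need at least one volume and one index")
  }
  mean(volumes) * mean(indices)
}

#' Derived immunological features
#'
#' Per patient and visit, from the raw panel values:
#' `rte_abs = rte_pct/100 * cd4_count` (cells/uL),
#' `cd4_cd8_ratio = cd4_count / cd8_count`,
#' `naive_memory_ratio = naive / memory` subset counts,
#' `trec_per_ml = sj_trec_per1e5 * pbmc_per_ml / 1e5`,
#' `sj_beta_ratio = sj_trec / sum of the six DJbeta1-TREC frequencies` (a
#' pre-summed `dj_trec_per1e5` column is accepted). Zero denominators yield
#' `NA` and are counted in the `"n_undefined"` attribute.
#'
#' @param cohort `recov_cohort` or long visits data.frame.
#' @param pbmc_per_ml PBMC concentration used for the per-mL TREC conversion;
#'   overridden by a `pbmc_per_ml` analyte when present.
#' @return wide data.frame keyed by `patient_id`, `time_months` with the raw
#'   analytes and every derivable feature.
#' @export
derived_features <- function(cohort, pbmc_per_ml = 1e6) {
  visits <- if (inherits(cohort, "recov_cohort")) cohort$visits else cohort
  wide <- stats::reshape(visits, idvar = c("patient_id", "time_months"),
                         timevar = "analyte", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$patient_id, wide$time_months), ]
  rownames(wide) <- NULL
  undef <- c(ratio = 0L, naive_memory = 0L, sj_beta = 0L)

  safe_div <- function(num, den, key) {
    out <- num / den
    bad <- !is.na(den) & den == 0
    out[bad] <- NA_real_
    undef[key] <<- sum(bad)
    out
  }
  if (all(c("cd4_count", "cd8_count") %in% names(wide))) {
    wide$cd4_cd8_ratio <- safe_div(wide$cd4_count, wide$cd8_count, "ratio")
  }
  if (all(c("rte_pct", "cd4_count") %in% names(wide))) {
    wide$rte_abs <- wide$rte_pct / 100 * wide$cd4_count
  }
  if (all(c("naive_count", "memory_count") %in% names(wide))) {
    wide$naive_memory_ratio <- safe_div(wide$naive_count, wide$memory_count,
                                        "naive_memory")
  }
  if ("sj_trec_per1e5" %in% names(wide)) {
    conc <- if ("pbmc_per_ml" %in% names(wide)) wide$pbmc_per_ml else
      pbmc_per_ml
    wide$trec_per_ml <- wide$sj_trec_per1e5 * conc / 1e5
    dj_cols <- grep("^dj[1-6]?_?b?1?_?trec", names(wide), value = TRUE)
    dj_cols <- setdiff(dj_cols, "dj_trec_per1e5")
    dj_sum <- if (length(dj_cols)) {
      rowSums(wide[, dj_cols, drop = FALSE])
    } else if ("dj_trec_per1e5" %in% names(wide)) {
      wide$dj_trec_per1e5
    } else NULL
    if (!is.null(dj_sum)) {
      wide$sj_beta_ratio <- safe_div(wide$sj_trec_per1e5, dj_sum, "sj_beta")
    }
  }
  attr(wide, "n_undefined") <- undef
  wide
}
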