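#' Names of the 24 trajectory summary measures
#'
#' Canonical order of the 24 per-trajectory summary statistics used by the
#' 3-step longitudinal clustering procedure (describe -> factor-select ->
#' cluster). First differences are successive value changes
#' `y[j+1] - y[j]`; second differences are successive changes of the first
#' differences.
#'
#' @return character vector of length 24.
#' @export
measure_names <- function() {
  c("range", "mean_over_time", "sd", "cv",
    "change", "mean_change_per_unit_time",
    "change_rel_first", "change_rel_mean",
    "slope", "r_squared",
    "max_first_diff", "sd_first_diff", "sd_first_diff_per_unit_time",
    "mean_abs_first_diff", "max_abs_first_diff",
    "max_abs_fd_to_mean", "max_abs_fd_to_slope", "sd_fd_to_slope",
    "mean_second_diff", "mean_abs_second_diff", "max_abs_second_diff",
    "max_abs_sd_to_mean", "max_abs_sd_to_max_abs_fd",
    "mean_abs_sd_to_mean_abs_fd")
}

#' Summary measures of one longitudinal trajectory
#'
#' Computes the 24 summary measures describing level, trend and fluctuation of
#' a single patient's series on the clustering window. Measures whose
#' denominator is zero (e.g. slope ratios of a flat series) are returned as
#' `NA` and listed in the `"undefined"` attribute rather than propagating
#' silently.
#'
#' @param series data.frame with `time_months` and `value` (as returned by
#'   [visit_series()]); at least 3 non-missing visits required.
#' @param window closed time interval used, default `c(0, 36)` months.
#' @return named numeric vector of length 24 with attribute `undefined`
#'   (character vector of measure names that could not be computed).
#' @export
compute_summary_measures <- function(series, window = c(0, 36)) {
  s <- series[!is.na(series$value) &
                series$time_months >= window[1] &
                series$time_months <= window[2], ]
  s <- s[order(s$time_months), ]
  t <- s$time_months
  y <- s$value
  n <- length(y)
  if (n < 3) stop("need >= 3 non-missing visits in the window")

  m <- stats::setNames(rep(NA_real_, 24), measure_names())
  ratio <- function(num, den) if (isTRUE(den != 0)) num / den else NA_real_

  m["range"] <- max(y) - min(y)
  m["mean_over_time"] <- mean(y)
  m["sd"] <- stats::sd(y)
  m["cv"] <- ratio(100 * m[["sd"]], m[["mean_over_time"]])
  m["change"] <- y[n] - y[1]
  m["mean_change_per_unit_time"] <- (y[n] - y[1]) / (t[n] - t[1])
  m["change_rel_first"] <- ratio(y[n] - y[1], y[1])
  m["change_rel_mean"] <- ratio(y[n] - y[1], m[["mean_over_time"]])
  # closed-form least squares: exactly zero slope for a constant series
  sxy <- sum((t - mean(t)) * (y - mean(y)))
  sxx <- sum((t - mean(t))^2)
  m["slope"] <- sxy / sxx
  resid <- y - (mean(y) - m[["slope"]] * mean(t)) - m[["slope"]] * t
  ss_tot <- sum((y - mean(y))^2)
  m["r_squared"] <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_

  fd <- diff(y)
  m["max_first_diff"] <- max(fd)
  m["sd_first_diff"] <- stats::sd(fd)
  m["sd_first_diff_per_unit_time"] <- stats::sd(fd / diff(t))
  m["mean_abs_first_diff"] <- mean(abs(fd))
  m["max_abs_first_diff"] <- max(abs(fd))
  m["max_abs_fd_to_mean"] <- ratio(m[["max_abs_first_diff"]],
                                   m[["mean_over_time"]])
  m["max_abs_fd_to_slope"] <- ratio(m[["max_abs_first_diff"]], m[["slope"]])
  m["sd_fd_to_slope"] <- ratio(m[["sd_first_diff"]], m[["slope"]])

  sdiff <- diff(fd)
  m["mean_second_diff"] <- mean(sdiff)
  m["mean_abs_second_diff"] <- mean(abs(sdiff))
  m["max_abs_second_diff"] <- max(abs(sdiff))
  m["max_abs_sd_to_mean"] <- ratio(m[["max_abs_second_diff"]],
                                   m[["mean_over_time"]])
  m["max_abs_sd_to_max_abs_fd"] <- ratio(m[["max_abs_second_diff"]],
                                         m[["max_abs_first_diff"]])
  m["mean_abs_sd_to_mean_abs_fd"] <- ratio(m[["mean_abs_second_diff"]],
                                           m[["mean_abs_first_diff"]])

  attr(m, "undefined") <- names(m)[is.na(m)]
  m
}

#' Summary-measure table for a whole cohort
#'
#' Applies [compute_summary_measures()] to every patient's series of `analyte`
#' on the window. Patients with fewer than 3 usable visits are excluded with a
#' warning.
#'
#' @inheritParams visit_series
#' @param analyte analyte clustered on, default CD4 count.
#' @param window closed months interval, default `c(0, 36)`.
#' @return data.frame: `patient_id` plus the 24 measure columns; attribute
#'   `excluded` lists dropped patients.
#' @export
cohort_summary_measures <- function(cohort, analyte = "cd4_count",
                                    window = c(0, 36)) {
  visits <- if (inherits(cohort, "recov_cohort")) cohort$visits else cohort
  ids <- unique(visits$patient_id)
  rows <- list()
  excluded <- character(0)
  for (id in ids) {
    s <- visit_series(visits, id, analyte, window)
    if (sum(!is.na(s$value)) < 3) {
      excluded <- c(excluded, id)
      next
    }
    rows[[id]] <- compute_summary_measures(s, window)
  }
  if (length(excluded)) {
    warning("excluded (fewer than 3 usable visits): ",
            paste(excluded, collapse = ", "))
  }
  if (!length(rows)) stop("no patient has >= 3 usable visits")
  out <- data.frame(patient_id = names(rows),
                    do.call(rbind, rows),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}
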