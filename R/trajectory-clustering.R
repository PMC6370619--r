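#' Factor selection among the trajectory measures
#'
#' Second step of the 3-step longitudinal clustering: principal component
#' analysis on the correlation matrix of the standardized summary measures;
#' factors with eigenvalue > 1 are retained and, for each, the measure with
#' the largest absolute loading is selected as its representative (distinct
#' across factors; ties broken by the canonical measure order).
#'
#' Measures undefined for some patient are imputed with the cohort median of
#' that measure (with a warning); measures constant across patients are
#' dropped before the PCA.
#'
#' @param measures data.frame from [cohort_summary_measures()].
#' @return list of class `"factor_selection"`: `eigenvalues`, `n_factors`,
#'   `selected` (representative measure per retained factor), `loadings`
#'   (their loadings), `dropped` (constant measures), `imputed` (measures that
#'   needed median imputation).
#' @export
select_measures_pca <- function(measures) {
  if (nrow(measures) < 2) stop("need >= 2 patients for factor selection")
  x <- as.matrix(measures[, setdiff(names(measures), "patient_id")])
  imputed <- character(0)
  for (j in seq_len(ncol(x))) {
    if (anyNA(x[, j])) {
      med <- stats::median(x[, j], na.rm = TRUE)
      if (is.na(med)) next  # entirely undefined; caught as constant below
      x[is.na(x[, j]), j] <- med
      imputed <- c(imputed, colnames(x)[j])
    }
  }
  if (length(imputed)) {
    warning("undefined measures imputed with cohort medians: ",
            paste(imputed, collapse = ", "))
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[is.na(sds) | sds == 0]
  keep <- setdiff(colnames(x), dropped)
  if (!length(keep)) stop("all measures are constant; nothing to select")
  x <- x[, keep, drop = FALSE]

  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pca$sdev^2
  n_factors <- max(sum(eig > 1), 1L)
  selected <- character(n_factors)
  loadings <- numeric(n_factors)
  taken <- character(0)
  for (k in seq_len(n_factors)) {
    load_k <- pca$rotation[, k]
    # canonical measure order breaks ties; already-chosen measures skipped so
    # the representatives are distinct
    ord <- order(-abs(load_k), match(names(load_k), measure_names()))
    pick <- names(load_k)[ord][!names(load_k)[ord] %in% taken][1]
    selected[k] <- pick
    loadings[k] <- load_k[pick]
    taken <- c(taken, pick)
  }
  structure(list(eigenvalues = eig, n_factors = n_factors,
                 selected = selected, loadings = loadings,
                 dropped = dropped, imputed = imputed),
            class = "factor_selection")
}

#' @export
print.factor_selection <- function(x, ...) {
  cat(sprintf("Factor selection: %d factor(s) with eigenvalue > 1\n",
              x$n_factors))
  for (k in seq_len(x$n_factors)) {
    cat(sprintf("  factor %d (eigenvalue %.3f): %s (loading %.3f)\n",
                k, x$eigenvalues[k], x$selected[k], x$loadings[k]))
  }
  invisible(x)
}

#' Cluster trajectories on the selected measures
#'
#' Third step of the 3-step procedure: k-means (50 seeded restarts, best
#' within-cluster sum of squares) on the representative measures.
#' Deterministic given `seed`; invariant to patient order.
#'
#' By default the selected measures enter k-means on their raw scales, so
#' level- and change-type measures (in the analyte's units) dominate the
#' dimensionless fluctuation-ratio measures. Standardizing instead
#' (`standardize = TRUE`) weights every representative equally, which lets
#' heavy-tailed ratio measures dominate the within-cluster sum of squares and
#' degrades recovery of well-separated trajectory groups (see the package
#' vignette).
#'
#' @param selection a [select_measures_pca()] result.
#' @param measures the measure table the selection came from.
#' @param k number of clusters (the study design fixes 2).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of random restarts.
#' @param standardize scale the selected measures to unit variance first.
#' @param cap_extremes winsorize each selected measure at the extreme-outlier
#'   fence (P25 - 3 IQR, P75 + 3 IQR) before clustering. The slope-ratio
#'   measures have heavy tails (near-zero slope denominators), and a single
#'   extreme value otherwise captures one of the k-means clusters.
#' @return data.frame `patient_id`, `cluster` (integer); cluster ids are in
#'   first-appearance order of the patient-id-sorted table, making the
#'   partition stable under patient reordering.
#' @export
cluster_trajectories <- function(selection, measures, k = 2, seed = 1L,
                                 nstart = 50, standardize = FALSE,
                                 cap_extremes = TRUE) {
  stopifnot(inherits(selection, "factor_selection"))
  if (k > nrow(measures)) stop("k exceeds the number of patients")
  x <- as.matrix(measures[, selection$selected, drop = FALSE])
  for (j in seq_len(ncol(x))) {
    if (anyNA(x[, j])) x[is.na(x[, j]), j] <- stats::median(x[, j],
                                                            na.rm = TRUE)
    if (cap_extremes) {
      fence <- extreme_outlier_fence(x[, j])
      x[, j] <- pmin(pmax(x[, j], fence$lower), fence$upper)
    }
  }
  ord <- order(measures$patient_id)  # patient-order invariance
  x <- x[ord, , drop = FALSE]
  if (standardize) x <- scale(x)
  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
  cl <- match(km$cluster, unique(km$cluster))  # first-seen order -> 1,2,...
  out <- data.frame(patient_id = measures$patient_id[ord],
                    cluster = as.integer(cl), stringsAsFactors = FALSE)
  out <- out[order(match(out$patient_id, measures$patient_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Did a CD4 series cross 500 cells/uL in the first 36 months?
#'
#' TRUE iff at least one value on the closed window is strictly above
#' 500 cells/uL (a value of exactly 500 does not count; the baseline visit is
#' part of the window).
#'
#' @param series data.frame `time_months`, `value`.
#' @param window closed months interval, default `c(0, 36)`.
#' @param threshold cells/uL, default 500.
#' @return logical scalar.
#' @export
classify_by_500_rule <- function(series, window = c(0, 36), threshold = 500) {
  s <- series[series$time_months >= window[1] &
                series$time_months <= window[2] & !is.na(series$value), ]
  if (nrow(s) == 0) stop("series empty on the window")
  max(s$value) > threshold
}

#' Label clusters as AIR / PIR
#'
#' The cluster with the larger fraction of patients whose 0-36-month CD4
#' maximum exceeds 500 cells/uL is labelled AIR (adequate immunological
#' responders); the other PIR. A tie in fractions is broken by the higher
#' cluster mean CD4, with a warning.
#'
#' @param assignment data.frame `patient_id`, `cluster` from
#'   [cluster_trajectories()].
#' @param cohort cohort (or long visits data.frame) holding the CD4 series.
#' @param window closed months interval for the 500 rule.
#' @return data.frame `patient_id`, `cluster`, `label` (`"AIR"`/`"PIR"`),
#'   `crossed_500`; attribute `cluster_summary` reports, per cluster, the
#'   count crossing 500.
#' @export
label_clusters <- function(assignment, cohort, window = c(0, 36)) {
  visits <- if (inherits(cohort, "recov_cohort")) cohort$visits else cohort
  crossed <- vapply(assignment$patient_id, function(id) {
    classify_by_500_rule(visit_series(visits, id, "cd4_count"), window)
  }, logical(1))
  mean_cd4 <- vapply(assignment$patient_id, function(id) {
    mean(visit_series(visits, id, "cd4_count", window)$value, na.rm = TRUE)
  }, numeric(1))
  clusters <- sort(unique(assignment$cluster))
  if (length(clusters) != 2) stop("expected exactly 2 clusters")
  frac <- vapply(clusters, function(cl) mean(crossed[assignment$cluster == cl]),
                 numeric(1))
  if (frac[1] == frac[2]) {
    warning("tie in 500-crossing fractions; labelling by cluster mean CD4")
    means <- vapply(clusters, function(cl) {
      mean(mean_cd4[assignment$cluster == cl])
    }, numeric(1))
    air_cluster <- clusters[which.max(means)]
  } else {
    air_cluster <- clusters[which.max(frac)]
  }
  out <- assignment
  out$label <- ifelse(out$cluster == air_cluster, "AIR", "PIR")
  out$crossed_500 <- unname(crossed)
  attr(out, "cluster_summary") <- data.frame(
    cluster = clusters,
    n = as.vector(table(factor(assignment$cluster, levels = clusters))),
    n_crossed_500 = vapply(clusters, function(cl) {
      sum(crossed[assignment$cluster == cl])
    }, numeric(1)),
    label = ifelse(clusters == air_cluster, "AIR", "PIR")
  )
  out
}

#' Full 3-step trajectory clustering of a cohort
#'
#' Convenience wrapper: summary measures on the window, PCA factor selection,
#' seeded k-means, AIR/PIR labelling by the 500 cells/uL rule.
#'
#' @inheritParams cohort_summary_measures
#' @inheritParams cluster_trajectories
#' @return labelled assignment (see [label_clusters()]) with attributes
#'   `selection` and `measures`.
#' @export
cluster_cohort <- function(cohort, analyte = "cd4_count", window = c(0, 36),
                           k = 2, seed = 1L) {
  measures <- cohort_summary_measures(cohort, analyte, window)
  selection <- select_measures_pca(measures)
  assignment <- cluster_trajectories(selection, measures, k = k, seed = seed)
  out <- label_clusters(assignment, cohort, window)
  attr(out, "selection") <- selection
  attr(out, "measures") <- measures
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, about 0 for independent ones. Used to score cluster
#' recovery against the true synthetic group labels.
#'
#' @param a,b vectors of cluster labels (any types coercible to factor).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
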