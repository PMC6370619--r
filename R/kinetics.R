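#' Exponential immune-recovery model
#'
#' Mean CD4+ T cell count (cells/uL) or CD4/CD8 ratio at `t` months after ART
#' initiation under the asymptotic-recovery model
#' \deqn{X(t) = A + B\,[1 - \exp(-t/\tau)]}
#' where `A` is the level at ART onset, `A + B` the long-run plateau and `tau`
#' the timescale (months) over which the plateau is approached.
#'
#' @param A baseline level (cells/uL for counts, unitless for the ratio).
#' @param B maximum attainable increase over baseline; `A + B` is the plateau.
#' @param tau recovery timescale in months; must be positive.
#' @param t months since ART initiation; non-negative, vectorised.
#' @return `X(t)`, same length as `t`. `X(0)` equals `A` exactly.
#' @examples
#' evaluate_kinetics(130.1, 284.5, 31.9, c(0, 12, 36))
#' @export
evaluate_kinetics <- function(A, B, tau, t) {
  if (!all(is.finite(A), is.finite(B), is.finite(tau))) {
    stop("kinetic parameters A, B, tau must be finite numbers")
  }
  if (any(tau <= 0)) stop("'tau' must be > 0")
  if (any(t < 0)) stop("'t' (months on ART) must be >= 0")
  A + B * (1 - exp(-t / tau))
}

#' Long-run plateau of a recovery model
#'
#' The asymptote of `X(t) = A + B[1 - exp(-t/tau)]` as `t` grows, i.e. `A + B`.
#' Methods exist for raw parameters, [group_kinetics()] objects and fitted
#' [fit_recovery_nlme()] models (one value per patient group).
#'
#' @param object parameters or fitted model.
#' @param ... passed to methods.
#' @return named numeric vector of plateau values.
#' @examples
#' asymptote(130.1, B = 284.5)   # PIR CD4 plateau
#' @export
asymptote <- function(object, ...) UseMethod("asymptote")

#' @param B maximum increase, for the default (numeric `A`) method.
#' @rdname asymptote
#' @export
asymptote.default <- function(object, B, ...) {
  stopifnot(is.numeric(object), is.numeric(B))
  object + B
}

#' @rdname asymptote
#' @export
asymptote.group_kinetics <- function(object, ...) object$A + object$B

#' Per-group kinetic parameters for trajectory simulation
#'
#' Bundles the population parameters of the exponential recovery model with the
#' dispersion of the patient-level random deviations used by
#' [generate_trajectory()]: patient `i` follows
#' `A_i + B_i (1 - exp(-t/tau))` with `A_i ~ N(A, sigma_A^2)`,
#' `B_i ~ N(B, sigma_B^2)` and i.i.d. measurement noise `N(0, sigma_eps^2)`.
#'
#' @inheritParams evaluate_kinetics
#' @param sigma_A,sigma_B SDs of the patient-level deviations on `A` and `B`.
#' @param sigma_eps residual measurement SD.
#' @param floor lower bound applied to simulated values (1 cell/uL for counts,
#'   0.001 for the CD4/CD8 ratio).
#' @return an object of class `"group_kinetics"`.
#' @export
group_kinetics <- function(A, B, tau, sigma_A = 0, sigma_B = 0,
                           sigma_eps = 0, floor = 1) {
  vals <- c(A = A, B = B, tau = tau, sigma_A = sigma_A, sigma_B = sigma_B,
            sigma_eps = sigma_eps, floor = floor)
  if (!all(is.finite(vals))) stop("group_kinetics parameters must be finite")
  if (B < 0) stop("'B' must be >= 0")
  if (tau <= 0) stop("'tau' must be > 0")
  if (any(c(sigma_A, sigma_B, sigma_eps) < 0)) stop("SDs must be >= 0")
  structure(as.list(vals), class = "group_kinetics")
}

#' @export
print.group_kinetics <- function(x, ...) {
  cat(sprintf(
    "Recovery kinetics: X(t) = %.4g + %.4g [1 - exp(-t/%.4g)]\n", x$A, x$B,
    x$tau))
  cat(sprintf("  plateau A+B = %.4g;  sigma_A=%.3g sigma_B=%.3g sigma_eps=%.3g (floor %.3g)\n",
              x$A + x$B, x$sigma_A, x$sigma_B, x$sigma_eps, x$floor))
  invisible(x)
}
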