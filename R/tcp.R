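#' Logistic tumour control probability
#'
#' The dose-response curve `TCP(B) = 1 / (1 + exp(-(B - TCD50)/k))`, a
#' logistic in biologically effective dose. `TCD50` is the BED giving 50%
#' control; `k` (Gy) sets the width of the sigmoid (smaller k = steeper).
#' Evaluation is numerically stable for arbitrarily large `|B - TCD50|/k`
#' (it saturates to 0 or 1 rather than overflowing).
#'
#' @param bed biologically effective dose in Gy; vectorised.
#' @param tcd50 BED at 50% tumour control, Gy. May be negative: fits to
#'   high-control subsets can push the half-control point below zero.
#' @param k logistic scale in Gy; must be non-zero.
#' @return tumour control probability in (0, 1).
#' @examples
#' tcp(105.6, tcd50 = 48.3, k = 44.7)  # ~0.783
#' tcp(48.3, 48.3, 44.7)               # exactly 0.5
#' @export
tcp <- function(bed, tcd50, k) {
  check_k(k)
  stats::plogis((bed - tcd50) / k)
}

#' Normalised slope of the dose-response curve at TCD50
#'
#' `gamma50 = TCD50 / (4 k)`: the percent change in TCP per percent change in
#' dose, evaluated at the 50% control level. It equals `TCD50` times the
#' derivative of the logistic at its midpoint, `1/(4k)`.
#'
#' @param tcd50 BED at 50% control, Gy.
#' @param k logistic scale, Gy (non-zero).
#' @return dimensionless normalised slope.
#' @examples
#' gamma50(48.3, 44.7)   # ~0.27
#' gamma50(68.9, 20.5)   # ~0.84
#' gamma50(-60.2, 113.3) # ~-0.13
#' @export
gamma50 <- function(tcd50, k) {
  check_k(k)
  tcd50 / (4 * k)
}

#' Delta-method standard error of gamma50
#'
#' First-order propagation of the (TCD50, k) covariance through
#' `gamma50 = TCD50/(4k)`, using the full 2x2 covariance including the cross
#' term. The gradient is `(1/(4k), -TCD50/(4k^2))`.
#'
#' @inheritParams gamma50
#' @param covariance symmetric positive semi-definite 2x2 covariance matrix of
#'   `(tcd50, k)`.
#' @return standard error of gamma50 (dimensionless).
#' @export
gamma50_se <- function(tcd50, k, covariance) {
  check_k(k)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == c(2L, 2L)) || any(!is.finite(covariance))) {
    stop("`covariance` must be a finite 2x2 matrix.", call. = FALSE)
  }
  if (max(abs(covariance - t(covariance))) > 1e-8 * (1 + max(abs(covariance)))) {
    stop("`covariance` must be symmetric.", call. = FALSE)
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("`covariance` must be positive semi-definite.", call. = FALSE)
  }
  grad <- c(1 / (4 * k), -tcd50 / (4 * k^2))
  sqrt(max(0, drop(grad %*% covariance %*% grad)))
}

check_k <- function(k) {
  if (any(k == 0) || any(!is.finite(k))) {
    stop("`k` = 0 gives a degenerate (step-function) dose-response model.",
         call. = FALSE)
  }
  invisible(NULL)
}
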