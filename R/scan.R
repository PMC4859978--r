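#' Spearman rank correlation with tie-aware average ranks
#'
#' Rank correlation of two equal-length sequences using average ranks for
#' ties (the conventional Spearman definition; local-control values tie
#' frequently across cohorts). The p-value uses the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom, or an
#' optional permutation test for verification.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm number of permutations when `p_method = "permutation"`.
#' @param seed RNG seed for the permutation test.
#' @return list with `rho` and `p_value`; both `NA` when either input is
#'   constant (undefined correlation).
#' @examples
#' spearman_rho(1:10, (1:10)^2)  # rho = 1
#' @export
spearman_rho <- function(x, y, p_method = c("t", "permutation"),
                         n_perm = 1e4, seed = 1L) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length.", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("Need at least 3 paired observations.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (p_method == "t") {
    if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    with_seed(seed, function() {
      ref <- abs(rho)
      hits <- sum(replicate(n_perm, {
        abs(stats::cor(rank(x), rank(sample(y)))) >= ref - 1e-12
      }))
      (hits + 1) / (n_perm + 1)
    })
  }
  list(rho = rho, p_value = p)
}

#' Correlation of local control with BED over a grid of alpha/beta ratios
#'
#' Recomputes BED per cohort from its `(n, d)` pair at each alpha/beta value
#' in the grid and correlates it (Spearman) with 3-year local control, for
#' each dose point and dataset subset requested. This probes how sensitive
#' the dose-response association is to the assumed fractionation sensitivity.
#'
#' @param data cohort tibble in the [read_cohort()] schema.
#' @param alpha_beta grid of alpha/beta ratios in Gy (default
#'   `c(5, 8.6, 10, 15, 20)`).
#' @param dose_points dose points to evaluate (default both).
#' @param subsets dataset subsets (default full dataset and HF).
#' @param p_method passed to [spearman_rho()].
#' @return A tibble with columns `alpha_beta`, `dose_point`, `subset`, `n`,
#'   `rho`, `p_value`; cells with fewer than 3 points have `NA` correlation.
#' @examples
#' bed_correlation_scan(nsclc_cohort(), alpha_beta = 10)
#' @export
bed_correlation_scan <- function(data,
                                 alpha_beta = c(5, 8.6, 10, 15, 20),
                                 dose_points = c("isocenter", "ptv_edge"),
                                 subsets = c("all", "HF"),
                                 p_method = "t") {
  stopifnot(all(alpha_beta > 0))
  if (!"regimen" %in% names(data)) {
    data$regimen <- classify_regimen(data$n_fractions, data$fraction_dose_isoc)
  }
  grid <- tidyr::expand_grid(alpha_beta = alpha_beta,
                             dose_point = dose_points, subset = subsets)
  purrr::pmap_dfr(grid, function(alpha_beta, dose_point, subset) {
    rows <- if (subset == "all") rep(TRUE, nrow(data)) else data$regimen == subset
    dcol <- if (dose_point == "isocenter") "fraction_dose_isoc" else "fraction_dose_edge"
    d <- data[[dcol]][rows]
    n <- data$n_fractions[rows]
    lc <- data$lc3y[rows]
    if (sum(rows) < 3) {
      return(tibble::tibble(alpha_beta = alpha_beta, dose_point = dose_point,
                            subset = subset, n = sum(rows),
                            rho = NA_real_, p_value = NA_real_))
    }
    s <- spearman_rho(bed_lq(n, d, alpha_beta), lc, p_method = p_method)
    tibble::tibble(alpha_beta = alpha_beta, dose_point = dose_point,
                   subset = subset, n = sum(rows),
                   rho = s$rho, p_value = s$p_value)
  })
}

#' Correlation of local control with total absorbed dose
#'
#' Companion check to [bed_correlation_scan()]: the Spearman correlation of
#' 3-year local control with the total physical dose `n d` at each dose
#' point, ignoring fractionation. Total dose mixes very different biological
#' effects across schedules, so this correlation is expected to be weak.
#'
#' @inheritParams bed_correlation_scan
#' @return tibble with `dose_point`, `n`, `rho`, `p_value`.
#' @export
total_dose_correlation <- function(data, dose_points = c("isocenter", "ptv_edge")) {
  purrr::map_dfr(dose_points, function(dose_point) {
    dcol <- if (dose_point == "isocenter") "fraction_dose_isoc" else "fraction_dose_edge"
    s <- spearman_rho(data$n_fractions * data[[dcol]], data$lc3y)
    tibble::tibble(dose_point = dose_point, n = nrow(data),
                   rho = s$rho, p_value = s$p_value)
  })
}
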