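#' BED model parameters
#'
#' Bundles the parameters that define a biologically effective dose (BED)
#' model: the `alpha_beta` ratio and, for the linear-quadratic-linear (LQ-L)
#' variant, the fraction-dose threshold `dt` above which the dose-effect per
#' fraction becomes purely linear. When `dt` is `NULL` the model is pure LQ.
#'
#' All BED arithmetic in this package is parameterised by the ratio
#' alpha/beta alone; alpha and beta are never needed separately because the
#' LQ-L slope factor (alpha + 2 beta Dt)/alpha reduces to 1 + 2 Dt/(alpha/beta).
#'
#' @param alpha_beta alpha/beta ratio in Gy; must be positive.
#' @param dt fraction-dose threshold in Gy (LQ-L model), or `NULL` for pure LQ.
#' @return An object of class `bed_params`.
#' @examples
#' bed_params(10)           # LQ with alpha/beta = 10 Gy
#' bed_params(10, dt = 11)  # LQ-L with threshold 11 Gy
#' @export
bed_params <- function(alpha_beta = 10, dt = NULL) {
  stopifnot(is.numeric(alpha_beta), length(alpha_beta) == 1L)
  if (!is.finite(alpha_beta) || alpha_beta <= 0) {
    stop("`alpha_beta` must be a positive, finite dose ratio (Gy).", call. = FALSE)
  }
  if (!is.null(dt)) {
    stopifnot(is.numeric(dt), length(dt) == 1L)
    if (!is.finite(dt) || dt <= 0) {
      stop("`dt` must be a positive, finite fraction dose (Gy).", call. = FALSE)
    }
  }
  structure(list(alpha_beta = alpha_beta, dt = dt), class = "bed_params")
}

#' @export
print.bed_params <- function(x, ...) {
  if (is.null(x$dt)) {
    cat(sprintf("<bed_params> LQ, alpha/beta = %g Gy\n", x$alpha_beta))
  } else {
    cat(sprintf("<bed_params> LQ-L, alpha/beta = %g Gy, Dt = %g Gy\n",
                x$alpha_beta, x$dt))
  }
  invisible(x)
}

#' Biologically effective dose under the LQ model
#'
#' `BED = n d (1 + d / (alpha/beta))` for `n` fractions of `d` Gy.
#'
#' @param n_fractions number of fractions (>= 1); vectorised.
#' @param fraction_dose dose per fraction in Gy (> 0); vectorised.
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @return BED in Gy.
#' @examples
#' bed_lq(4, 12, 10)   # 105.6 Gy
#' bed_lq(3, 18, 10)   # 151.2 Gy
#' @export
bed_lq <- function(n_fractions, fraction_dose, alpha_beta = 10) {
  check_bed_inputs(n_fractions, fraction_dose, alpha_beta)
  n_fractions * fraction_dose * (1 + fraction_dose / alpha_beta)
}

#' Biologically effective dose under the LQ-L model
#'
#' Below the fraction-dose threshold `dt` the LQ-L model coincides with the
#' LQ model; at and above it the per-fraction effect continues linearly with
#' the slope the LQ curve has at `dt`:
#' `BED = n [ Dt (1 + Dt/(ab)) + (1 + 2 Dt/(ab)) (d - Dt) ]` for `d >= Dt`.
#' The two branches agree in value and first derivative at `d = Dt`.
#'
#' @inheritParams bed_lq
#' @param params a [bed_params()] object with a non-`NULL` `dt`, or a numeric
#'   `dt` when `alpha_beta` is given separately.
#' @param alpha_beta alpha/beta ratio in Gy; ignored when `params` is a
#'   `bed_params` object.
#' @return BED in Gy.
#' @examples
#' bed_lql(1, 35.03, bed_params(10, dt = 11))  # ~100 Gy
#' @export
bed_lql <- function(n_fractions, fraction_dose, params, alpha_beta = 10) {
  if (!inherits(params, "bed_params")) params <- bed_params(alpha_beta, dt = params)
  if (is.null(params$dt)) {
    stop("LQ-L BED needs a fraction-dose threshold: supply `dt` in `bed_params()`.",
         call. = FALSE)
  }
  check_bed_inputs(n_fractions, fraction_dose, params$alpha_beta)
  ab <- params$alpha_beta
  dt <- params$dt
  ifelse(
    fraction_dose < dt,
    n_fractions * fraction_dose * (1 + fraction_dose / ab),
    n_fractions * (dt * (1 + dt / ab) + (1 + 2 * dt / ab) * (fraction_dose - dt))
  )
}

#' Evaluate a BED model given parameters
#'
#' Dispatches to [bed_lq()] or [bed_lql()] depending on whether `params`
#' carries a fraction-dose threshold.
#'
#' @inheritParams bed_lq
#' @param params a [bed_params()] object.
#' @return BED in Gy.
#' @export
bed <- function(n_fractions, fraction_dose, params = bed_params()) {
  stopifnot(inherits(params, "bed_params"))
  if (is.null(params$dt)) {
    bed_lq(n_fractions, fraction_dose, params$alpha_beta)
  } else {
    bed_lql(n_fractions, fraction_dose, params)
  }
}

#' Fraction dose needed to reach a target BED (closed-form isoeffect inversion)
#'
#' Inverts the BED model exactly. For LQ the inverse is the positive root of
#' `d^2/(ab) + d - B/n = 0`. For LQ-L, if the per-fraction target effect is at
#' most the LQ effect at `dt` the LQ root applies, otherwise the linear branch
#' is inverted: `d = Dt + (B/n - Dt (1 + Dt/ab)) / (1 + 2 Dt/ab)`.
#'
#' @param target_bed target BED in Gy (> 0); vectorised.
#' @param n_fractions number of fractions over which the target is delivered.
#' @param params a [bed_params()] object.
#' @return dose per fraction in Gy.
#' @examples
#' fraction_dose_for_bed(100, 1, bed_params(10))           # ~27.0 Gy
#' fraction_dose_for_bed(100, 1, bed_params(10, dt = 11))  # ~35.0 Gy
#' @export
fraction_dose_for_bed <- function(target_bed, n_fractions, params = bed_params()) {
  stopifnot(inherits(params, "bed_params"))
  if (any(!is.finite(target_bed)) || any(target_bed <= 0)) {
    stop("`target_bed` must be positive and finite.", call. = FALSE)
  }
  if (any(n_fractions < 1)) {
    stop("`n_fractions` must be at least 1.", call. = FALSE)
  }
  ab <- params$alpha_beta
  per_fraction <- target_bed / n_fractions
  # positive quadratic root of d (1 + d/ab) = per_fraction
  d_lq <- ab / 2 * (-1 + sqrt(1 + 4 * per_fraction / ab))
  if (is.null(params$dt)) {
    return(d_lq)
  }
  dt <- params$dt
  knee <- dt * (1 + dt / ab) # per-fraction BED at the threshold
  ifelse(
    per_fraction <= knee,
    d_lq,
    dt + (per_fraction - knee) / (1 + 2 * dt / ab)
  )
}

#' Spread in required fraction dose across a set of BED models
#'
#' For a target BED delivered in `n_fractions`, computes the required dose per
#' fraction under every model in `model_set` and returns the maximum minus the
#' minimum. The default set contrasts LQ with alpha/beta of 8, 10 and 15 Gy
#' against LQ-L with alpha/beta 10 Gy and an 11 Gy threshold.
#'
#' @param target_bed target BED in Gy.
#' @param n_fractions number of fractions.
#' @param model_set a non-empty list of [bed_params()] objects.
#' @return maximum minus minimum required fraction dose, in Gy.
#' @examples
#' model_discrepancy(100, 1)  # ~10.5 Gy
#' model_discrepancy(200, 1)  # ~30.1 Gy
#' @export
model_discrepancy <- function(target_bed, n_fractions,
                              model_set = discrepancy_model_set()) {
  stopifnot(is.list(model_set), length(model_set) >= 1L)
  doses <- vapply(
    model_set,
    function(p) fraction_dose_for_bed(target_bed, n_fractions, p),
    numeric(length(target_bed))
  )
  if (length(target_bed) == 1L) doses <- matrix(doses, nrow = 1L)
  apply(doses, 1L, max) - apply(doses, 1L, min)
}

#' @rdname model_discrepancy
#' @export
discrepancy_model_set <- function() {
  list(
    bed_params(8), bed_params(10), bed_params(15),
    bed_params(10, dt = 11)
  )
}

#' Isoeffect table across fraction numbers and BED models
#'
#' Tabulates the fraction dose required to reach each `target_bed` for
#' `1:max_fractions` fractions under every model in `model_set`, together with
#' the per-(target, n) model spread.
#'
#' @inheritParams model_discrepancy
#' @param max_fractions largest fraction number tabulated.
#' @return A tibble with columns `target_bed`, `n_fractions`, `model`,
#'   `fraction_dose`, and `discrepancy` (spread across models, repeated within
#'   each (target, n) cell).
#' @export
isoeffect_table <- function(target_bed = c(100, 200), max_fractions = 10,
                            model_set = discrepancy_model_set()) {
  labels <- vapply(model_set, function(p) {
    if (is.null(p$dt)) sprintf("LQ a/b=%g", p$alpha_beta)
    else sprintf("LQ-L a/b=%g Dt=%g", p$alpha_beta, p$dt)
  }, character(1))
  grid <- tidyr::expand_grid(
    target_bed = target_bed,
    n_fractions = seq_len(max_fractions),
    model = labels
  )
  grid$fraction_dose <- purrr::pmap_dbl(
    grid[c("target_bed", "n_fractions", "model")],
    function(target_bed, n_fractions, model) {
      fraction_dose_for_bed(target_bed, n_fractions,
                            model_set[[match(model, labels)]])
    }
  )
  dplyr::mutate(
    dplyr::group_by(grid, .data$target_bed, .data$n_fractions),
    discrepancy = max(.data$fraction_dose) - min(.data$fraction_dose)
  ) |>
    dplyr::ungroup()
}

check_bed_inputs <- function(n_fractions, fraction_dose, alpha_beta) {
  if (any(!is.finite(alpha_beta)) || any(alpha_beta <= 0)) {
    stop("`alpha_beta` must be a positive, finite dose ratio (Gy).", call. = FALSE)
  }
  if (any(n_fractions < 1)) {
    stop("`n_fractions` must be at least 1.", call. = FALSE)
  }
  if (any(fraction_dose < 0)) {
    stop("`fraction_dose` must be non-negative.", call. = FALSE)
  }
  invisible(NULL)
}
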