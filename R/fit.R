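#' Optimiser controls for [fit_tcp()]
#'
#' @param starts number of multi-start points (the nominal start plus
#'   `starts - 1` jittered copies); guards against the shallow likelihood of
#'   high-control subsets.
#' @param seed RNG seed for the start-point jitter (the caller's RNG state is
#'   left untouched).
#' @param reltol relative convergence tolerance on the residual sum of squares.
#' @param maxit iteration cap per optimiser run.
#' @param bounds named list of length-2 numeric ranges for `tcd50`, `k`, `dt`
#'   and `alpha_beta`. `tcd50` may be negative: shallow fits to high-control
#'   subsets can place the half-control point below zero.
#' @return A list of class `tcp_fit_control`.
#' @export
tcp_fit_control <- function(starts = 5L, seed = 1L, reltol = 1e-10,
                            maxit = 2000L,
                            bounds = list(tcd50 = c(-500, 500),
                                          k = c(0.1, 500),
                                          dt = c(0.5, 30),
                                          alpha_beta = c(0.1, 100))) {
  structure(list(starts = as.integer(starts), seed = as.integer(seed),
                 reltol = reltol, maxit = as.integer(maxit), bounds = bounds),
            class = "tcp_fit_control")
}

#' Fit a logistic TCP curve to cohort local-control data
#'
#' Minimises the weighted residual sum of squares
#' `sum_i w_i (LC_i - TCP(BED_i(theta); theta))^2` over the free parameters of
#' the chosen model variant, by bounded multi-start quasi-Newton optimisation.
#' Standard errors come from the Gauss-Newton approximation
#' `sigma^2 (J' W J)^-1` at the optimum; 68% confidence intervals from
#' likelihood profiling (Gaussian likelihood with the residual variance
#' profiled out); p-values are two-sided Wald tests against zero.
#'
#' Model variants:
#' * `"lq"` — LQ BED at fixed `alpha_beta`; free `tcd50`, `k`.
#' * `"lql"` — LQ-L BED at fixed `alpha_beta`; free `tcd50`, `k`, `dt`.
#' * `"free_ab"` — LQ BED with free `alpha_beta`; free `tcd50`, `k`,
#'   `alpha_beta`.
#'
#' Weighting defaults to the cohort patient counts, which treats each cohort
#' proportion with a precision proportional to its size; `"unit"` weights every
#' data point equally. With `anchored = TRUE` a pseudo-observation at BED = 0
#' and TCP = 0 with `anchor_weight` times the largest data weight constrains
#' the curve towards the origin.
#'
#' @param data cohort tibble in the [read_cohort()] schema.
#' @param variant model variant; see Details.
#' @param dose_point dose specification point the BED is evaluated at.
#' @param subset fit the full dataset or the CF/HF class alone.
#' @param alpha_beta fixed alpha/beta ratio (Gy) for the `lq` and `lql`
#'   variants; starting value for `free_ab`.
#' @param weights `"n_patients"` (default) or `"unit"`.
#' @param anchored add the origin pseudo-point (default off).
#' @param anchor_weight weight multiplier for the pseudo-point, relative to the
#'   largest data weight.
#' @param profile compute 68% profile-likelihood intervals for every free
#'   parameter (default). Turn off in simulation loops for speed; they can be
#'   recovered later with [profile_ci()].
#' @param level confidence level for the profile intervals.
#' @param control a [tcp_fit_control()] list.
#' @return An object of class `tcp_fit`; see [tidy.tcp_fit()],
#'   [glance.tcp_fit()], [profile_ci()], [lr_test()].
#' @examples
#' fit <- fit_tcp(nsclc_cohort(), profile = FALSE)
#' coef(fit)
#' @export
fit_tcp <- function(data,
                    variant = c("lq", "lql", "free_ab"),
                    dose_point = c("isocenter", "ptv_edge"),
                    subset = c("all", "CF", "HF"),
                    alpha_beta = 10,
                    weights = c("n_patients", "unit"),
                    anchored = FALSE,
                    anchor_weight = 1000,
                    profile = TRUE,
                    level = 0.68,
                    control = tcp_fit_control()) {
  variant <- match.arg(variant)
  dose_point <- match.arg(dose_point)
  subset <- match.arg(subset)
  weights <- match.arg(weights)
  stopifnot(inherits(control, "tcp_fit_control"))

  if (subset != "all") {
    if (!"regimen" %in% names(data)) {
      data$regimen <- classify_regimen(data$n_fractions, data$fraction_dose_isoc)
    }
    data <- data[data$regimen == subset, , drop = FALSE]
  }
  if (nrow(data) == 0) stop("No data points in the requested subset.", call. = FALSE)

  dcol <- if (dose_point == "isocenter") "fraction_dose_isoc" else "fraction_dose_edge"
  n <- data$n_fractions
  d <- data[[dcol]]
  lc <- data$lc3y
  w <- if (weights == "n_patients") as.numeric(data$n_patients) else rep(1, nrow(data))
  if (anchored) w_anchor <- anchor_weight * max(w)

  params <- switch(variant,
                   lq = c("tcd50", "k"),
                   lql = c("tcd50", "k", "dt"),
                   free_ab = c("tcd50", "k", "alpha_beta"))
  lower <- vapply(params, function(p) control$bounds[[p]][1], numeric(1))
  upper <- vapply(params, function(p) control$bounds[[p]][2], numeric(1))

  bed_theta <- switch(variant,
    lq = {
      b0 <- bed_lq(n, d, alpha_beta)
      function(theta) b0
    },
    lql = function(theta) bed_lql(n, d, bed_params(alpha_beta, dt = theta[3])),
    free_ab = function(theta) bed_lq(n, d, theta[3])
  )
  predict_theta <- function(theta) {
    p <- stats::plogis((bed_theta(theta) - theta[1]) / theta[2])
    if (anchored) p <- c(p, stats::plogis(-theta[1] / theta[2]))
    p
  }
  obs <- if (anchored) c(lc, 0) else lc
  wts <- if (anchored) c(w, w_anchor) else w
  clamp <- function(theta) pmin(pmax(theta, lower), upper)
  rss_fn <- function(theta) {
    theta <- clamp(theta)
    sum(wts * (obs - predict_theta(theta))^2)
  }

  # start values: TCD50 at the subset's median BED, k at a quarter of the BED
  # range, Dt = 10 Gy, alpha/beta = 10 Gy; plus jittered copies.
  bed_start <- bed_lq(n, d, if (variant == "free_ab") 10 else alpha_beta)
  base <- c(tcd50 = stats::median(bed_start),
            k = max(diff(range(bed_start)) / 4, 1),
            dt = 10, alpha_beta = 10)[params]
  starts <- with_seed(control$seed, function() {
    lapply(seq_len(control$starts), function(i) {
      if (i == 1) return(base)
      jit <- base
      jit["tcd50"] <- jit["tcd50"] + stats::rnorm(1, 0, 0.25 * max(diff(range(bed_start)), 10))
      jit["k"] <- jit["k"] * exp(stats::rnorm(1, 0, 0.35))
      if ("dt" %in% params) jit["dt"] <- jit["dt"] * exp(stats::rnorm(1, 0, 0.3))
      if ("alpha_beta" %in% params) {
        jit["alpha_beta"] <- jit["alpha_beta"] * exp(stats::rnorm(1, 0, 0.3))
      }
      clamp(jit)
    })
  })

  run_one <- function(start) {
    o1 <- stats::optim(start, rss_fn, method = "Nelder-Mead",
                       control = list(maxit = control$maxit,
                                      reltol = control$reltol))
    o2 <- tryCatch(
      stats::optim(clamp(o1$par), rss_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = control$maxit, factr = 1e2)),
      error = function(e) o1)
    best <- if (o2$value <= o1$value) o2 else o1
    best$par <- clamp(best$par)
    # the polish step may abort its line search on flat plateaus after the
    # Nelder-Mead stage has already converged; either clean exit counts
    best$ok <- (o1$convergence == 0L) || (o2$convergence == 0L)
    best
  }
  fits <- lapply(starts, run_one)
  rss_all <- vapply(fits, `[[`, numeric(1), "value")
  ord <- order(rss_all, if ("dt" %in% params) {
    vapply(fits, function(f) f$par["dt"], numeric(1))
  } else rss_all)
  fit <- fits[[ord[1]]]
  theta <- stats::setNames(fit$par, params)
  rss <- max(fit$value, 1e-12)
  converged <- is.finite(rss) && isTRUE(fit$ok)

  n_obs <- length(obs)
  p <- length(params)
  fitted_vals <- predict_theta(theta)
  resid <- obs - fitted_vals
  # Gauss-Newton covariance at the optimum
  J <- tryCatch(numDeriv::jacobian(function(th) predict_theta(th), theta),
                error = function(e) NULL)
  sigma2 <- rss / max(n_obs - p, 1)
  cov <- NULL
  se <- rep(NA_real_, p)
  if (!is.null(J) && all(is.finite(J))) {
    JtWJ <- t(J) %*% (wts * J)
    cov <- tryCatch(sigma2 * solve(JtWJ), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se <- ifelse(dg >= 0, sqrt(pmax(dg, 0)), NA_real_)
    }
  }
  if (!is.null(cov)) dimnames(cov) <- list(params, params)
  names(se) <- params
  p_values <- 2 * stats::pnorm(-abs(theta / se))

  loglik <- gaussian_loglik(rss, n_obs, wts)
  g50 <- gamma50(theta["tcd50"], theta["k"])
  g50_se <- if (!is.null(cov)) {
    tryCatch(gamma50_se(theta["tcd50"], theta["k"],
                        cov[c("tcd50", "k"), c("tcd50", "k")]),
             error = function(e) NA_real_)
  } else NA_real_

  out <- structure(list(
    estimates = theta, se = se, p_values = p_values, cov = cov,
    rss = rss, loglik = loglik, aic = 2 * (p + 1) - 2 * loglik,
    gamma50 = unname(g50), gamma50_se = unname(g50_se),
    n_points = nrow(data), n_obs = n_obs, n_free = p,
    converged = converged, multistart_rss = sort(rss_all),
    variant = variant, alpha_beta_fixed = if (variant == "free_ab") NA_real_ else alpha_beta,
    dose_point = dose_point, subset = subset, weights = weights,
    anchored = anchored,
    fit_data = tibble::tibble(n_fractions = n, fraction_dose = d, lc = lc,
                              weight = w),
    obs = obs, wts = wts, fitted = fitted_vals, residuals = resid,
    predict_theta = predict_theta, rss_fn = rss_fn,
    lower = lower, upper = upper, control = control,
    ci_level = level,
    call = match.call()
  ), class = "tcp_fit")
  out$ci <- if (profile) {
    do.call(rbind, lapply(params, function(pp) profile_ci(out, pp, level)))
  } else {
    matrix(NA_real_, p, 2, dimnames = list(params, c("lower", "upper")))
  }
  rownames(out$ci) <- params
  out
}

# Weighted Gaussian log-likelihood with the variance profiled out
# (the convention stats::logLik uses for least-squares fits).
gaussian_loglik <- function(rss, n, w) {
  0.5 * sum(log(w)) - n / 2 * (log(2 * pi) + 1 - log(n) + log(max(rss, 1e-12)))
}

#' Profile-likelihood confidence interval for one TCP fit parameter
#'
#' Scans the parameter while re-optimising all remaining free parameters, and
#' returns the interval where the profiled Gaussian log-likelihood
#' `-(n/2) log RSS(theta)` stays within `qchisq(level, 1)/2` of its maximum.
#' An endpoint that does not cross before the parameter's search bound is
#' reported as `NA` (a half-open interval, as happens for weakly identified
#' parameters).
#'
#' @param fit a [fit_tcp()] result.
#' @param param name of a free parameter of the fit.
#' @param level confidence level (default 0.68, i.e. roughly +-1 SE).
#' @return named numeric vector `c(lower, upper)`, possibly containing `NA`.
#' @export
profile_ci <- function(fit, param, level = 0.68) {
  stopifnot(inherits(fit, "tcp_fit"))
  params <- names(fit$estimates)
  j <- match(param, params)
  if (is.na(j)) {
    stop(sprintf("`%s` is not a free parameter of this fit (%s).",
                 param, paste(params, collapse = ", ")), call. = FALSE)
  }
  n <- fit$n_obs
  drop_target <- stats::qchisq(level, df = 1) / 2
  others <- setdiff(seq_along(params), j)

  prof_rss <- function(v, start) {
    if (length(others) == 0) return(fit$rss_fn(v))
    make_theta <- function(th_o) {
      theta <- numeric(length(params))
      theta[j] <- v
      theta[others] <- th_o
      theta
    }
    if (length(others) == 1) {
      o <- stats::optimize(function(x) fit$rss_fn(make_theta(x)),
                           lower = fit$lower[others], upper = fit$upper[others],
                           tol = 1e-8)
      o$objective
    } else {
      o <- stats::optim(start, function(x) fit$rss_fn(make_theta(x)),
                        method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-11))
      o$value
    }
  }
  # signed log-likelihood drop relative to the optimum
  g <- function(v, start) {
    n / 2 * (log(max(prof_rss(v, start), 1e-12)) - log(fit$rss)) - drop_target
  }
  est <- fit$estimates[j]
  start_o <- fit$estimates[others]
  step0 <- max(fit$se[j], abs(est) * 0.1, 1, na.rm = TRUE)

  find_edge <- function(dir) {
    bound <- if (dir < 0) fit$lower[j] else fit$upper[j]
    v_in <- est
    step <- step0
    for (i in 1:60) {
      v <- v_in + dir * step
      hit_bound <- (dir < 0 && v <= bound) || (dir > 0 && v >= bound)
      if (hit_bound) v <- bound
      gv <- g(v, start_o)
      if (is.finite(gv) && gv > 0) {
        r <- stats::uniroot(function(x) g(x, start_o),
                            lower = min(v_in, v), upper = max(v_in, v),
                            tol = max(1e-5, abs(est) * 1e-6))
        return(r$root)
      }
      if (hit_bound) return(NA_real_) # profile never crossed: open endpoint
      v_in <- v
      step <- step * 1.8
    }
    NA_real_
  }
  c(lower = find_edge(-1), upper = find_edge(+1))
}

#' Likelihood-ratio test between nested TCP fits
#'
#' Scale-free Gaussian likelihood-ratio statistic `n log(RSS_reduced /
#' RSS_full)` for two fits of the same data where the reduced model's free
#' parameters are a subset of the full model's (LQ nested in LQ-L). The
#' statistic is referred to a chi-squared distribution with `df` equal to the
#' difference in free-parameter count. A full-model RSS above the reduced
#' one (an optimiser artifact) is clipped to a zero statistic with a warning.
#'
#' @param reduced,full `tcp_fit` objects fitted to the same observations,
#'   dose point and weights.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, and the two
#'   RSS values.
#' @export
lr_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "tcp_fit"), inherits(full, "tcp_fit"))
  if (reduced$n_obs != full$n_obs ||
      reduced$dose_point != full$dose_point ||
      reduced$subset != full$subset ||
      !isTRUE(all.equal(reduced$obs, full$obs)) ||
      !isTRUE(all.equal(reduced$wts, full$wts))) {
    stop("`reduced` and `full` must be fitted to the same observations, ",
         "dose point and weights.", call. = FALSE)
  }
  df <- full$n_free - reduced$n_free
  if (df < 0 || !all(names(reduced$estimates) %in% names(full$estimates))) {
    stop("`reduced` must be nested in `full`.", call. = FALSE)
  }
  stat <- reduced$n_obs * log(reduced$rss / full$rss)
  if (stat < 0) {
    warning("Full-model RSS exceeds the reduced model's; statistic clipped at 0 ",
            "(optimiser artifact).", call. = FALSE)
    stat <- 0
  }
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 rss_reduced = reduced$rss, rss_full = full$rss)
}

#' Shapiro-Wilk normality check of the fit residuals
#'
#' Tests the weighted residuals `sqrt(w_i) (LC_i - TCP_i)` for normality and
#' returns the quantile pairs for a Q-Q plot. With fewer than 3 residuals or
#' (numerically) constant residuals the test is unavailable and `NA`s are
#' returned instead of an error.
#'
#' @param fit a [fit_tcp()] result.
#' @return list with `statistic`, `p_value`, and `qq`, a tibble of
#'   (`theoretical`, `sample`) quantiles of the standardised residuals.
#' @export
residual_normality <- function(fit) {
  stopifnot(inherits(fit, "tcp_fit"))
  r <- sqrt(fit$wts) * fit$residuals
  if (length(r) < 3 || stats::sd(r) < 1e-12) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                qq = tibble::tibble(theoretical = numeric(), sample = numeric())))
  }
  sw <- stats::shapiro.test(r)
  z <- sort((r - mean(r)) / stats::sd(r))
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       qq = tibble::tibble(theoretical = stats::qnorm(stats::ppoints(length(z))),
                           sample = z))
}

#' @export
coef.tcp_fit <- function(object, ...) object$estimates

#' @export
vcov.tcp_fit <- function(object, ...) object$cov

#' @export
fitted.tcp_fit <- function(object, ...) object$fitted

#' @export
residuals.tcp_fit <- function(object, ...) object$residuals

#' @export
nobs.tcp_fit <- function(object, ...) object$n_obs

#' @export
logLik.tcp_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free + 1, nobs = object$n_obs,
            class = "logLik")
}

#' Predict tumour control probability from a fitted curve
#'
#' @param object a `tcp_fit`.
#' @param bed BED values (Gy) to evaluate the fitted curve at; defaults to the
#'   BEDs of the fitted data points under the fitted model.
#' @param ... unused.
#' @return numeric vector of control probabilities.
#' @export
predict.tcp_fit <- function(object, bed = NULL, ...) {
  th <- object$estimates
  if (is.null(bed)) {
    dat <- object$fit_data
    bp <- switch(object$variant,
                 lq = bed_params(object$alpha_beta_fixed),
                 lql = bed_params(object$alpha_beta_fixed, dt = th[["dt"]]),
                 free_ab = bed_params(th[["alpha_beta"]]))
    bed <- bed(dat$n_fractions, dat$fraction_dose, bp)
  }
  tcp(bed, th[["tcd50"]], th[["k"]])
}

#' @export
print.tcp_fit <- function(x, digits = 3, ...) {
  lab <- switch(x$variant,
                lq = sprintf("LQ (alpha/beta = %g Gy)", x$alpha_beta_fixed),
                lql = sprintf("LQ-L (alpha/beta = %g Gy)", x$alpha_beta_fixed),
                free_ab = "LQ (free alpha/beta)")
  cat(sprintf("Logistic TCP fit: %s, %s, %s subset%s\n", lab, x$dose_point,
              x$subset, if (x$anchored) ", origin-anchored" else ""))
  cat(sprintf("%d data points, %s weights%s\n", x$n_points, x$weights,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  tab <- data.frame(estimate = x$estimates, std.error = x$se,
                    ci68_low = x$ci[, "lower"], ci68_high = x$ci[, "upper"],
                    p.value = x$p_values)
  print(round(tab, digits))
  cat(sprintf("gamma50 %.3g (SE %.3g)   RSS %.4g   logLik %.4g   AIC %.4g\n",
              x$gamma50, x$gamma50_se, x$rss, x$loglik, x$aic))
  invisible(x)
}

#' Tidy a TCP fit into one row per parameter
#'
#' @param x a `tcp_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `p.value`,
#'   `conf.low`, `conf.high` (68% profile interval).
#' @method tidy tcp_fit
#' @export
tidy.tcp_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$se),
    p.value = unname(x$p_values),
    conf.low = unname(x$ci[, "lower"]),
    conf.high = unname(x$ci[, "upper"])
  )
}

#' One-row summary of a TCP fit
#'
#' @param x a `tcp_fit`.
#' @param ... unused.
#' @return tibble with the goodness-of-fit record: `rss`, `logLik`, `AIC`,
#'   `gamma50` and its standard error, point/parameter counts and convergence.
#' @method glance tcp_fit
#' @export
glance.tcp_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, dose_point = x$dose_point, subset = x$subset,
    weights = x$weights, anchored = x$anchored,
    rss = x$rss, logLik = x$loglik, AIC = x$aic,
    gamma50 = x$gamma50, gamma50_se = x$gamma50_se,
    n_points = x$n_points, n_free = x$n_free, converged = x$converged
  )
}

#' Plot a fitted TCP curve over its data
#'
#' Local control against BED (under the fitted model's parameters), point area
#' proportional to the fit weight, with the fitted logistic curve overlaid.
#'
#' @param object a `tcp_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tcp_fit
#' @export
autoplot.tcp_fit <- function(object, ...) {
  th <- object$estimates
  dat <- object$fit_data
  bp <- switch(object$variant,
               lq = bed_params(object$alpha_beta_fixed),
               lql = bed_params(object$alpha_beta_fixed, dt = th[["dt"]]),
               free_ab = bed_params(th[["alpha_beta"]]))
  dat$bed <- bed(dat$n_fractions, dat$fraction_dose, bp)
  grid <- tibble::tibble(bed = seq(0, max(dat$bed) * 1.05, length.out = 200))
  grid$tcp <- tcp(grid$bed, th[["tcd50"]], th[["k"]])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bed)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$lc, size = .data$weight),
                        alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$tcp),
                       colour = "firebrick") +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = "BED [Gy]", y = "3-year local control",
                  size = "weight") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
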