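fixture <- nsclc_cohort()

test_that("noise-free synthetic data is recovered essentially exactly", {
  sim <- simulate_cohort(cohort_sim_spec(tcd50 = 48, k = 45, noise = "none",
                                         seed = 8))
  fit <- fit_tcp(sim, "lq", profile = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(48, 45), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
  # LQ-L truth recovered by the LQ-L variant
  sim2 <- simulate_cohort(cohort_sim_spec(tcd50 = 48, k = 45, dt = 11,
                                          noise = "none", seed = 9))
  fit2 <- fit_tcp(sim2, "lql", profile = FALSE)
  expect_equal(unname(coef(fit2)), c(48, 45, 11), tolerance = 1e-3)
})

test_that("a dense grid search brackets the two-parameter optimum", {
  fit <- fit_tcp(fixture, "lq", profile = FALSE)
  b <- bed_lq(fixture$n_fractions, fixture$fraction_dose_isoc, 10)
  w <- fixture$n_patients
  rss_at <- function(tcd50, k) {
    sum(w * (fixture$lc3y - plogis((b - tcd50) / k))^2)
  }
  # coarse pass over the spec'd search box, then a 0.5 Gy refinement
  coarse <- expand.grid(tcd50 = seq(-200, 200, by = 4),
                        k = seq(2, 300, by = 4))
  coarse$rss <- mapply(rss_at, coarse$tcd50, coarse$k)
  top <- coarse[which.min(coarse$rss), ]
  fine <- expand.grid(tcd50 = seq(top$tcd50 - 4, top$tcd50 + 4, by = 0.5),
                      k = seq(max(top$k - 4, 0.5), top$k + 4, by = 0.5))
  fine$rss <- mapply(rss_at, fine$tcd50, fine$k)
  best_grid <- fine[which.min(fine$rss), ]
  expect_lte(fit$rss, best_grid$rss + 1e-10)
  expect_lt(abs(coef(fit)[["tcd50"]] - best_grid$tcd50), 1)
  expect_lt(abs(coef(fit)[["k"]] - best_grid$k), 1)
})

test_that("the fit agrees with an independent Levenberg-Marquardt solver", {
  skip_if_not_installed("minpack.lm")
  fit <- fit_tcp(fixture, "lq", profile = FALSE)
  df <- data.frame(
    b = bed_lq(fixture$n_fractions, fixture$fraction_dose_isoc, 10),
    lc = fixture$lc3y, w = fixture$n_patients
  )
  nls_fit <- minpack.lm::nlsLM(
    lc ~ 1 / (1 + exp(-(b - tcd50) / k)), data = df, weights = w,
    start = list(tcd50 = 80, k = 40),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14)
  )
  expect_equal(unname(coef(fit)), unname(coef(nls_fit)), tolerance = 1e-4)
})

test_that("anchoring the origin moves the slope far more than TCD50", {
  free <- fit_tcp(fixture, "lq", weights = "unit", profile = FALSE)
  anch <- fit_tcp(fixture, "lq", weights = "unit", anchored = TRUE,
                  profile = FALSE)
  d_tcd50 <- abs(coef(anch)[["tcd50"]] - coef(free)[["tcd50"]])
  d_k <- abs(coef(anch)[["k"]] - coef(free)[["k"]])
  expect_lt(d_tcd50, d_k)
  # under patient weighting the same holds on the relative scale
  freew <- fit_tcp(fixture, "lq", profile = FALSE)
  anchw <- fit_tcp(fixture, "lq", anchored = TRUE, profile = FALSE)
  expect_lt(abs(coef(anchw)[["tcd50"]] / coef(freew)[["tcd50"]] - 1),
            abs(coef(anchw)[["k"]] / coef(freew)[["k"]] - 1))
  # the anchored curve passes close to the origin
  expect_lt(tcp(0, coef(anch)[["tcd50"]], coef(anch)[["k"]]), 0.05)
})

test_that("weighting scheme and subsets are honoured", {
  wfit <- fit_tcp(fixture, "lq", weights = "n_patients", profile = FALSE)
  ufit <- fit_tcp(fixture, "lq", weights = "unit", profile = FALSE)
  expect_gt(abs(coef(wfit)[["tcd50"]] - coef(ufit)[["tcd50"]]), 0.5)
  cf <- fit_tcp(fixture, "lq", subset = "CF", profile = FALSE)
  expect_equal(cf$n_points, 8)
  hf <- fit_tcp(fixture, "lq", subset = "HF", profile = FALSE)
  expect_equal(hf$n_points, 26)
  expect_error(fit_tcp(fixture[0, ], "lq"), "No data points")
})

test_that("profile intervals approach Wald intervals when the surface is quadratic", {
  # large cohorts + many schedules give a well-conditioned, near-Gaussian fit
  sc <- tibble::tibble(n_fractions = rep(c(1, 3, 5, 8, 20, 35), 4),
                       fraction_dose_isoc = rep(c(24, 15, 11, 7.5, 3, 2), 4))
  spec <- cohort_sim_spec(tcd50 = 48, k = 45, schedules = sc,
                          cohort_sizes = 500, seed = 77)
  fit <- fit_tcp(simulate_cohort(spec), "lq", profile = FALSE)
  z <- qnorm(1 - (1 - 0.68) / 2)
  for (p in c("tcd50", "k")) {
    ci <- profile_ci(fit, p, 0.68)
    wald <- coef(fit)[[p]] + c(-1, 1) * z * fit$se[[p]]
    expect_equal(unname(ci), wald, tolerance = 0.15)
  }
})

test_that("profile intervals contain the estimate and match Table-style output", {
  fit <- fit_tcp(fixture, "lq")
  expect_true(fit$ci["tcd50", "lower"] < coef(fit)[["tcd50"]])
  expect_true(fit$ci["tcd50", "upper"] > coef(fit)[["tcd50"]])
  td <- tidy(fit)
  expect_equal(td$term, c("tcd50", "k"))
  expect_true(all(c("estimate", "std.error", "p.value", "conf.low",
                    "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$AIC, 2 * (fit$n_free + 1) - 2 * gl$logLik)
  expect_equal(AIC(fit), gl$AIC)
  expect_equal(gl$gamma50, gamma50(coef(fit)[["tcd50"]], coef(fit)[["k"]]))
  expect_error(profile_ci(fit, "dt"), "not a free parameter")
})

test_that("weakly identified parameters give open (NA) profile endpoints", {
  # the free-alpha/beta likelihood valley is flat towards large k: the upper
  # profile endpoint never crosses before the search bound
  fit <- fit_tcp(fixture, "free_ab", profile = FALSE)
  ci <- profile_ci(fit, "k", 0.68)
  expect_true(is.na(ci[["upper"]]))
  expect_true(is.finite(ci[["lower"]]))
})

test_that("likelihood-ratio test is zero on self and chi-squared on nested fits", {
  lq <- fit_tcp(fixture, "lq", profile = FALSE)
  lql <- fit_tcp(fixture, "lql", profile = FALSE)
  self <- lr_test(lq, lq)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  nested <- lr_test(lq, lql)
  expect_equal(nested$df, 1)
  expect_equal(nested$statistic,
               lq$n_obs * log(lq$rss / lql$rss), tolerance = 1e-12)
  expect_equal(nested$p_value,
               pchisq(nested$statistic, 1, lower.tail = FALSE))
  other <- fit_tcp(fixture, "lq", dose_point = "ptv_edge", profile = FALSE)
  expect_error(lr_test(other, lql), "same observations")
})

test_that("residual normality check is calibrated and degenerates gracefully", {
  spec <- cohort_sim_spec(tcd50 = 48, k = 45, seed = 13)
  ps <- vapply(1:40, function(i) {
    sp <- spec; sp$seed <- 1000L + i
    fit <- fit_tcp(simulate_cohort(sp), "lq", profile = FALSE)
    residual_normality(fit)$p_value
  }, numeric(1))
  # binomial sampling noise is near-normal at these cohort sizes
  expect_gte(mean(ps > 0.05), 0.8)
  expect_equal(nrow(residual_normality(fit_tcp(fixture, "lq",
                                               profile = FALSE))$qq), 34)
  # heavy-tailed contamination is flagged (median over replicates)
  base <- simulate_cohort(cohort_sim_spec(tcd50 = 48, k = 45, noise = "none",
                                          seed = 3))
  set.seed(3)
  p_t <- vapply(1:11, function(i) {
    sim <- base
    sim$lc3y <- pmin(pmax(sim$lc3y + 0.08 * rt(nrow(sim), df = 1), 0), 1)
    residual_normality(fit_tcp(sim, "lq", profile = FALSE))$p_value
  }, numeric(1))
  expect_lt(median(p_t), 0.05)
  # too few residuals: unavailable marker, not an error
  two <- base[1:2, ]
  fit2 <- suppressWarnings(fit_tcp(two, "lq", profile = FALSE))
  expect_true(is.na(residual_normality(fit2)$p_value))
})
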