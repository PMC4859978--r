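#' Specification for a synthetic cohort dataset
#'
#' Defines the generating truth for simulated cohort tables: a logistic TCP
#' curve coupled to a BED model, a schedule grid, cohort sizes and the noise
#' model. Local control for each schedule is a binomial proportion of the
#' cohort's patients, the dispersion structure cohort-level outcome reviews
#' actually have; an optional beta-binomial multiplier adds the extra
#' between-study heterogeneity real collections show.
#'
#' @param tcd50,k true logistic parameters (Gy).
#' @param alpha_beta true alpha/beta ratio (Gy).
#' @param dt true fraction-dose threshold (Gy) for an LQ-L truth, or `NULL`
#'   for LQ.
#' @param schedules tibble with columns `n_fractions`, `fraction_dose_isoc`
#'   and optionally `edge_ratio` (isocenter-to-edge dose ratio per schedule).
#'   Default: the 34 schedules of [nsclc_cohort()] with their observed ratios.
#' @param edge_ratio fallback isocenter-to-edge dose ratio when `schedules`
#'   has none (default 0.8, the most common prescription isodose).
#' @param cohort_sizes a length-2 vector is interpreted as a `c(min, max)`
#'   range to draw cohort sizes from uniformly (default `c(25, 180)`,
#'   mirroring the packaged dataset); any other length is recycled across
#'   schedules as fixed sizes.
#' @param noise `"binomial"` (default) or `"none"` (exact TCP values).
#' @param overdispersion beta-binomial intra-class correlation in `[0, 1)`;
#'   0 (default) is pure binomial sampling.
#' @param seed RNG seed; every simulation is deterministic given the spec.
#' @return list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(tcd50 = 48, k = 45, alpha_beta = 10, dt = NULL,
                            schedules = NULL, edge_ratio = 0.8,
                            cohort_sizes = c(25, 180),
                            noise = c("binomial", "none"),
                            overdispersion = 0, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(schedules)) {
    fx <- nsclc_cohort()
    schedules <- tibble::tibble(
      n_fractions = fx$n_fractions,
      fraction_dose_isoc = fx$fraction_dose_isoc,
      edge_ratio = fx$fraction_dose_edge / fx$fraction_dose_isoc
    )
  }
  stopifnot(nrow(schedules) >= 1,
            all(c("n_fractions", "fraction_dose_isoc") %in% names(schedules)))
  if (!"edge_ratio" %in% names(schedules)) schedules$edge_ratio <- edge_ratio
  stopifnot(overdispersion >= 0, overdispersion < 1)
  structure(list(tcd50 = tcd50, k = k, alpha_beta = alpha_beta, dt = dt,
                 schedules = schedules, cohort_sizes = cohort_sizes,
                 noise = noise, overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a cohort outcome table from a known TCP curve
#'
#' For each schedule, computes the BED under the true model, evaluates the
#' true TCP, and draws the observed control count from
#' `Binomial(n_patients, TCP)` (or reports TCP exactly with `noise = "none"`).
#' The output uses the [read_cohort()] schema, so every downstream stage of
#' the package consumes simulated data unchanged.
#'
#' @param spec a [cohort_sim_spec()].
#' @return cohort tibble with one row per schedule, including the true
#'   control probability in a `tcp_true` column.
#' @examples
#' sim <- simulate_cohort(cohort_sim_spec(seed = 42))
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  sc <- spec$schedules
  m <- nrow(sc)
  with_seed(spec$seed, function() {
    n_pats <- if (length(spec$cohort_sizes) == 2) {
      sample(spec$cohort_sizes[1]:spec$cohort_sizes[2], m, replace = TRUE)
    } else {
      rep_len(spec$cohort_sizes, m)
    }
    bp_true <- bed_params(spec$alpha_beta, dt = spec$dt)
    bed_true <- bed(sc$n_fractions, sc$fraction_dose_isoc, bp_true)
    p_true <- tcp(bed_true, spec$tcd50, spec$k)
    lc <- if (spec$noise == "none") {
      p_true
    } else {
      p_draw <- if (spec$overdispersion > 0) {
        rho <- spec$overdispersion
        shape <- (1 - rho) / rho
        stats::rbeta(m, p_true * shape, (1 - p_true) * shape)
      } else p_true
      stats::rbinom(m, n_pats, p_draw) / n_pats
    }
    d_edge <- sc$fraction_dose_isoc * sc$edge_ratio
    out <- tibble::tibble(
      study_id = sprintf("sim-%02d", seq_len(m)),
      n_patients = n_pats,
      n_fractions = sc$n_fractions,
      total_dose = sc$n_fractions * sc$fraction_dose_isoc,
      fraction_dose_isoc = sc$fraction_dose_isoc,
      fraction_dose_edge = d_edge,
      bed10_isoc = bed_lq(sc$n_fractions, sc$fraction_dose_isoc, 10),
      bed10_edge = bed_lq(sc$n_fractions, d_edge, 10),
      lc3y_pct = 100 * lc,
      lc3y = lc,
      tcp_true = p_true
    )
    out$regimen <- classify_regimen(out$n_fractions, out$fraction_dose_isoc)
    out
  })
}

#' Parameter-recovery experiment on simulated cohorts
#'
#' Repeatedly simulates a cohort table from `spec` and refits it, returning
#' per-replicate estimates and a per-parameter summary (bias, median absolute
#' bias, RMSE, and 68% profile-CI coverage when `coverage = TRUE`).
#' Replicate-level fit failures are counted, not fatal. Replicate seeds are
#' derived deterministically from `spec$seed`.
#'
#' @param spec a [cohort_sim_spec()]; its parameters are the recovery truth.
#' @param n_replicates number of simulated datasets (>= 2).
#' @param variant,weights passed to [fit_tcp()].
#' @param coverage also compute profile CIs per replicate and report their
#'   empirical coverage of the truth (slower).
#' @param level CI level used for coverage.
#' @return list with `replicates` (tibble of per-replicate estimates),
#'   `summary` (per-parameter bias/RMSE/coverage) and `n_failed`.
#' @export
recovery_experiment <- function(spec, n_replicates = 200,
                                variant = c("lq", "lql", "free_ab"),
                                weights = "n_patients",
                                coverage = FALSE, level = 0.68) {
  stopifnot(inherits(spec, "cohort_sim_spec"), n_replicates >= 2)
  variant <- match.arg(variant)
  truth <- c(tcd50 = spec$tcd50, k = spec$k,
             dt = spec$dt %||% NA_real_, alpha_beta = spec$alpha_beta)
  reps <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    spec_i <- spec
    spec_i$seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    sim <- simulate_cohort(spec_i)
    fit <- tryCatch(
      fit_tcp(sim, variant = variant, weights = weights,
              alpha_beta = spec$alpha_beta, profile = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(tibble::tibble(replicate = i, term = NA_character_,
                            estimate = NA_real_, covered = NA))
    }
    ci <- if (coverage) {
      do.call(rbind, lapply(names(fit$estimates), function(p)
        profile_ci(fit, p, level)))
    } else NULL
    tibble::tibble(
      replicate = i,
      term = names(fit$estimates),
      estimate = unname(fit$estimates),
      covered = if (coverage) {
        tv <- truth[names(fit$estimates)]
        lo <- ifelse(is.na(ci[, 1]), -Inf, ci[, 1])
        hi <- ifelse(is.na(ci[, 2]), Inf, ci[, 2])
        # numerical guard: perfect (zero-residual) fits collapse the profile
        # interval to a point at the optimiser's resolution
        ntol <- 1e-4 * (1 + abs(tv))
        tv >= lo - ntol & tv <= hi + ntol
      } else NA
    )
  })
  n_failed <- sum(is.na(reps$term)) # one NA row per failed replicate
  ok <- reps[!is.na(reps$term), , drop = FALSE]
  summary <- ok |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      truth = unname(truth[.data$term[1]]),
      bias = mean(.data$estimate) - .data$truth,
      median_abs_bias = stats::median(abs(.data$estimate - .data$truth)),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = if (coverage) mean(.data$covered) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  list(replicates = ok, summary = summary, n_failed = n_failed)
}
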