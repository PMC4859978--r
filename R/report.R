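#' Run the full cohort dose-response analysis
#'
#' Orchestrates the complete analysis over one cohort table: every standard
#' fit variant (LQ on the full/CF/HF subsets, LQ-L on the full/HF subsets,
#' free-alpha/beta LQ on the full/CF subsets, each at both dose points — 14
#' fits), the nested LQ vs LQ-L likelihood-ratio tests, the alpha/beta
#' correlation scan, per-regimen cohort summaries, and the isoeffect
#' model-discrepancy table. Results are returned as a list of tibbles and,
#' when `out_dir` is given, written as CSV files next to a JSON manifest
#' recording the configuration so a run is reproducible from the manifest and
#' the input table alone.
#'
#' @param data cohort tibble (default: the packaged dataset).
#' @param out_dir directory to write CSV outputs and `manifest.json` into, or
#'   `NULL` (default) to only return results.
#' @param seed seed for the fit multi-starts.
#' @param alpha_beta fixed alpha/beta ratio for the LQ/LQ-L fits (Gy).
#' @param alpha_beta_grid grid for the correlation scan (Gy).
#' @param bed_targets BED levels for the isoeffect discrepancy table (Gy).
#' @param max_fractions largest fraction number in the isoeffect table.
#' @param weights fit weighting scheme, see [fit_tcp()].
#' @param anchored fit with the origin constraint (default off).
#' @param profile compute profile CIs for every fit (default; disable for a
#'   fast pass).
#' @return list with elements `fits` (parameter table, one row per fitted
#'   parameter plus fit-level columns), `fit_summaries`, `lr_tests`, `scan`,
#'   `summaries`, `isoeffect`, and `manifest`.
#' @examples
#' \donttest{
#' res <- run_full_analysis(nsclc_cohort(), profile = FALSE)
#' res$fit_summaries
#' }
#' @export
run_full_analysis <- function(data = nsclc_cohort(), out_dir = NULL, seed = 1L,
                              alpha_beta = 10,
                              alpha_beta_grid = c(5, 8.6, 10, 15, 20),
                              bed_targets = c(100, 200), max_fractions = 10,
                              weights = "n_patients", anchored = FALSE,
                              profile = TRUE) {
  plan <- dplyr::bind_rows(
    tidyr::expand_grid(variant = "lq", subset = c("all", "CF", "HF"),
                       dose_point = c("isocenter", "ptv_edge")),
    tidyr::expand_grid(variant = "lql", subset = c("all", "HF"),
                       dose_point = c("isocenter", "ptv_edge")),
    tidyr::expand_grid(variant = "free_ab", subset = c("all", "CF"),
                       dose_point = c("isocenter", "ptv_edge"))
  )
  ctrl <- tcp_fit_control(seed = seed)
  fits <- purrr::pmap(plan, function(variant, subset, dose_point) {
    fit_tcp(data, variant = variant, dose_point = dose_point, subset = subset,
            alpha_beta = alpha_beta, weights = weights, anchored = anchored,
            profile = profile, control = ctrl)
  })
  fit_params <- purrr::map2_dfr(fits, seq_len(nrow(plan)), function(f, i) {
    dplyr::bind_cols(plan[i, ], tidy(f))
  })
  fit_summaries <- purrr::map_dfr(fits, glance)

  key <- function(variant, subset, dose_point) {
    which(plan$variant == variant & plan$subset == subset &
            plan$dose_point == dose_point)
  }
  lr_tests <- purrr::pmap_dfr(
    tidyr::expand_grid(subset = c("all", "HF"),
                       dose_point = c("isocenter", "ptv_edge")),
    function(subset, dose_point) {
      lrt <- lr_test(fits[[key("lq", subset, dose_point)]],
                     fits[[key("lql", subset, dose_point)]])
      dplyr::bind_cols(tibble::tibble(subset = subset, dose_point = dose_point),
                       lrt)
    })

  scan <- bed_correlation_scan(data, alpha_beta = alpha_beta_grid)
  summaries <- purrr::map_dfr(
    c("bed10_isoc", "bed10_edge", "lc3y_pct", "n_patients", "followup_months"),
    function(f) {
      if (!f %in% names(data)) return(NULL)
      dplyr::mutate(cohort_summary(data, f), field = f, .before = 1)
    })
  isoeffect <- isoeffect_table(bed_targets, max_fractions)

  manifest <- list(
    package = "radbed",
    version = as.character(utils::packageVersion("radbed")),
    seed = seed,
    config = list(alpha_beta = alpha_beta, alpha_beta_grid = alpha_beta_grid,
                  bed_targets = bed_targets, max_fractions = max_fractions,
                  weights = weights, anchored = anchored, profile = profile),
    n_points = nrow(data),
    n_patients = sum(data$n_patients),
    config_hash = rlang::hash(list(alpha_beta, alpha_beta_grid, bed_targets,
                                   max_fractions, weights, anchored, seed))
  )

  out <- list(fits = fit_params, fit_summaries = fit_summaries,
              lr_tests = lr_tests, scan = scan, summaries = summaries,
              isoeffect = isoeffect, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("fits", "fit_summaries", "lr_tests", "scan", "summaries",
                 "isoeffect")) {
      readr::write_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Plot the isoeffect model-discrepancy table
#'
#' Fraction dose required to reach each target BED against fraction number,
#' one line per BED model, faceted by target.
#'
#' @param table output of [isoeffect_table()].
#' @return a ggplot object.
#' @export
plot_isoeffect <- function(table = isoeffect_table()) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$n_fractions, y = .data$fraction_dose,
                               colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~.data$target_bed, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(breaks = unique(table$n_fractions)) +
    ggplot2::labs(x = "number of fractions", y = "dose per fraction [Gy]",
                  colour = "BED model") +
    ggplot2::theme_minimal()
}
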