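# Bisection oracle for BED inversion: solves bed(n, d, params) = target on
# d in (0, 200] without using the closed form under test.
bisect_fraction_dose <- function(target_bed, n_fractions, params,
                                 interval = c(1e-9, 200), tol = 1e-9) {
  stats::uniroot(
    function(d) bed(n_fractions, d, params) - target_bed,
    interval = interval, tol = tol
  )$root
}

# Brute-force Spearman: rank both sides (average ranks), then Pearson.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Midpoint-convention median oracle via explicit sorting.
median_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# A small, fully valid cohort table for IO and summary tests.
make_toy_cohort <- function(n_rows = 6, seed = 99) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    n <- sample(c(3:5, 30:35), n_rows, replace = TRUE)
    d_isoc <- ifelse(n <= 10, runif(n_rows, 8, 20), runif(n_rows, 1.5, 3))
    d_edge <- d_isoc * 0.8
    tibble::tibble(
      study_id = sprintf("toy-%02d", seq_len(n_rows)),
      n_patients = sample(25:120, n_rows, replace = TRUE),
      n_fractions = n,
      total_dose = n * d_isoc,
      fraction_dose_isoc = d_isoc,
      fraction_dose_edge = d_edge,
      bed10_isoc = bed_lq(n, d_isoc, 10),
      bed10_edge = bed_lq(n, d_edge, 10),
      lc3y_pct = round(runif(n_rows, 50, 99), 1)
    )
  })
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}
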