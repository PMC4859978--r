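test_that("packaged cohort table has the documented structure", {
  co <- nsclc_cohort()
  expect_equal(nrow(co), 34)
  expect_equal(sum(co$n_patients), 2319)
  expect_equal(as.integer(table(co$regimen)[c("CF", "HF")]), c(8L, 26L))
  expect_true(all(co$lc3y >= 0 & co$lc3y <= 1))
  expect_true(all(co$n_patients >= 25))
  expect_true(all(co$bed10_isoc >= co$bed10_edge))
  # stored fraction doses reproduce the BED columns well within 1%
  expect_equal(bed_lq(co$n_fractions, co$fraction_dose_isoc, 10),
               co$bed10_isoc, tolerance = 1e-4)
  expect_equal(bed_lq(co$n_fractions, co$fraction_dose_edge, 10),
               co$bed10_edge, tolerance = 1e-4)
  # ambiguous source rows are flagged and explained
  expect_true(is.logical(co$flagged) && any(co$flagged))
  expect_true(all(nzchar(co$notes[co$flagged])))
})

test_that("fraction-dose reconstruction inverts the LQ formula", {
  expect_equal(reconstruct_fraction_dose(105.6, 4, 10), 12)
  expect_equal(reconstruct_fraction_dose(74.3, 35, 10),
               bisect_fraction_dose(74.3, 35, bed_params(10)),
               tolerance = 1e-6)
  set.seed(31)
  n <- sample(1:40, 80, replace = TRUE)
  d <- runif(80, 0.5, 30)
  ab <- runif(80, 1, 25)
  expect_equal(reconstruct_fraction_dose(bed_lq(n, d, ab), n, ab), d,
               tolerance = 1e-9)
  expect_error(reconstruct_fraction_dose(-1, 4, 10), "positive")
  expect_error(reconstruct_fraction_dose(100, 4, 0), "positive")
})

test_that("regimen classification follows the fraction-number/dose windows", {
  expect_equal(classify_regimen(1, 30), "HF")
  expect_equal(classify_regimen(58, 1.2), "CF")
  expect_equal(classify_regimen(12, 7), "unclassified")
  expect_equal(classify_regimen(8, 6), "HF")    # 6 Gy boundary, few fractions
  expect_equal(classify_regimen(20, 1.0), "unclassified")
  expect_equal(classify_regimen(c(1, 30, 12), c(20, 2, 7)),
               c("HF", "CF", "unclassified"))
  expect_error(classify_regimen(0, 5), "n_fractions")
})

test_that("cohort summaries agree with a sort-based oracle", {
  co <- nsclc_cohort()
  s <- cohort_summary(co, "bed10_isoc")
  for (g in c("CF", "HF")) {
    v <- co$bed10_isoc[co$regimen == g]
    row <- s[s$regimen == g, ]
    expect_equal(row$median, median_oracle(v))
    expect_equal(c(row$min, row$max), range(v))
    expect_equal(row$n, length(v))
  }
  set.seed(5)
  for (i in 1:10) {
    toy <- make_toy_cohort(n_rows = sample(3:9, 1), seed = i)
    toy$lc3y <- toy$lc3y_pct / 100
    toy$regimen <- classify_regimen(toy$n_fractions, toy$fraction_dose_isoc)
    s <- cohort_summary(toy, "lc3y", by_regimen = FALSE)
    expect_equal(s$median, median_oracle(toy$lc3y))
  }
  # a single record is its own median, min and max
  one <- co[3, ]
  s1 <- cohort_summary(one, "bed10_isoc", by_regimen = FALSE)
  expect_equal(unlist(s1[c("median", "min", "max")], use.names = FALSE),
               rep(one$bed10_isoc, 3))
  expect_error(cohort_summary(co, "not_a_column"), "not found")
})

test_that("reading cohort files validates schema and row invariants", {
  toy <- make_toy_cohort()
  path <- write_cohort_csv(toy)
  x <- read_cohort(path)
  expect_equal(nrow(x), nrow(toy))
  expect_equal(x$lc3y, toy$lc3y_pct / 100)
  expect_true(all(c("lc3y", "regimen") %in% names(x)))

  # tab-separated variant is auto-detected
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(toy, tsv)
  expect_equal(read_cohort(tsv)$bed10_isoc, x$bed10_isoc)

  # header-only file yields an empty, well-formed table
  empty <- write_cohort_csv(toy[0, ])
  expect_equal(nrow(read_cohort(empty)), 0)

  # missing mandatory column is a schema error
  p2 <- write_cohort_csv(toy[setdiff(names(toy), "bed10_isoc")])
  expect_error(read_cohort(p2), "bed10_isoc")

  # non-numeric dose reports the offending row
  toy3 <- toy
  toy3$fraction_dose_isoc <- as.character(toy3$fraction_dose_isoc)
  toy3$fraction_dose_isoc[2] <- "twelve"
  expect_error(read_cohort(write_cohort_csv(toy3)), "row")

  # invariant violations are rejected with row diagnostics
  toy4 <- toy
  toy4$n_patients[3] <- 10
  expect_error(read_cohort(write_cohort_csv(toy4)), "25 patients.*3")
  toy5 <- toy
  toy5$bed10_edge[1] <- toy5$bed10_isoc[1] + 5
  expect_error(read_cohort(write_cohort_csv(toy5)), "bed10_isoc < bed10_edge")
  toy6 <- toy
  toy6$fraction_dose_isoc[4] <- toy6$fraction_dose_isoc[4] * 1.2
  expect_error(read_cohort(write_cohort_csv(toy6)), "inconsistent")
  expect_error(read_cohort(tempfile()), "not found")
})
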