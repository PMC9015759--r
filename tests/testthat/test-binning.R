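test_that("explicit-edge binning honours the closure conventions", {
  pm <- default_schemes()[["AvgDailyPM25"]]
  # first interval closed both ends, later ones (a, b]
  expect_equal(as.character(apply_explicit(c(3.27, 6.30, 6.31, 7.81, 10.83), pm)),
               c("[3.27, 6.30]", "[3.27, 6.30]", "(6.30, 7.81]",
                 "(6.30, 7.81]", "(7.81, 10.83]"))
  # out-of-range values go missing with a warning
  expect_warning(out <- apply_explicit(c(2.0, 11.0, 5.0), pm), "outside")
  expect_equal(is.na(out), c(TRUE, TRUE, FALSE))
  expect_equal(as.character(apply_explicit(NA, pm)), NA_character_)

  road <- default_schemes()[["RoadwayDistance"]]
  # integer half-open [a, a+50) bins; boundary 50 belongs to the next bin
  expect_equal(as.character(apply_explicit(c(49.9, 50.0, 0, 249.99, 250, 5000), road)),
               c("0-49", "50-99", "0-49", "200-249", ">=250", ">=250"))
})

test_that("every in-range value maps to exactly one bin (partition scan)", {
  schemes <- default_schemes()
  for (nm in c("ProbNoInsurance", "MedianIncome", "AvgDailyPM25",
               "MaxDailyOzone", "RoadwayDistance")) {
    s <- schemes[[nm]]
    hi <- if (is.infinite(s$edges[length(s$edges)])) {
      s$edges[length(s$edges) - 1] * 3
    } else {
      s$edges[length(s$edges)]
    }
    grid <- unique(c(seq(s$edges[1], hi, length.out = 2001), s$edges[is.finite(s$edges)]))
    labels <- suppressWarnings(as.character(apply_explicit(grid, s)))
    in_range <- if (s$closure == "left_closed") grid >= s$edges[1]
                else grid >= s$edges[1] & grid <= hi
    expect_true(all(!is.na(labels[in_range])), info = nm)
    expect_true(all(labels[in_range] %in% s$labels), info = nm)
  }
})

test_that("age binning computes completed years and enforces the 89-year cap", {
  # age 4 and age 89 land in their bins; age 90 is excluded with a flag
  bd <- as.Date(c("2011-06-15", "1926-06-15", "1925-06-15", "2015-12-31"))
  out <- bin_age(bd, 2016)
  expect_equal(as.character(out), c("<5", "65-89", NA, "<5"))
  expect_equal(attr(out, "excluded"), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(attr(out, "age"), c(4, 89, 90, 0))
  # cap-to-top keeps the row in the oldest permissible bin
  capped <- bin_age(bd, 2016, cap_to_top = TRUE)
  expect_equal(as.character(capped)[3], "65-89")
  # birth after the reference date is a hard error
  expect_error(bin_age(as.Date("2016-06-01"), 2016), class = "validation_error")
  # boundary: born exactly on Jan 1 has a completed birthday that day
  expect_equal(as.character(bin_age(as.Date("2011-01-01"), 2016)), "5-17")
})

test_that("frequency binning matches the quantile oracle and balances counts", {
  # uniform distinct values split exactly evenly
  s <- fit_frequency_quantiles(1:10, k = 5)
  counts <- table(as.character(apply_explicit(1:10, s)))
  expect_true(all(counts == 2))

  set.seed(42)
  v <- rlnorm(10000, meanlog = 10, sdlog = 0.6)
  k <- 4
  s <- fit_frequency_quantiles(v, k)
  expect_equal(s$edges, quantile_oracle(v, seq(0, 1, length.out = k + 1)),
               tolerance = 1e-12)
  counts <- as.integer(table(factor(as.character(apply_explicit(v, s)),
                                    levels = s$labels)))
  expect_true(all(abs(counts - 10000 / k) <= 1))

  expect_error(fit_frequency_quantiles(rep(3, 50), 4), class = "degenerate_input_error")
  expect_error(fit_frequency_quantiles(1:3, 5), class = "degenerate_input_error")
})

test_that("value-cut binning spans the range in equal widths", {
  s <- fit_value_cut(c(0, 2, 5, 9), k = 3)
  expect_equal(s$edges, c(0, 3, 6, 9))
  # the minimum belongs to the first (closed) interval
  expect_equal(as.character(apply_explicit(0, s)), s$labels[1])
  set.seed(11)
  v <- rnorm(2000)
  s <- fit_value_cut(v, 5)
  lab <- as.character(apply_explicit(v, s))
  oracle <- vapply(v, rebin_oracle, "", edges = s$edges, labels = s$labels)
  expect_equal(lab, oracle)
  expect_error(fit_value_cut(rep(1, 10), 3), class = "degenerate_input_error")
})

test_that("shipped default schemes carry the published bin edges", {
  s <- default_schemes()
  expect_equal(s$MedianIncome$edges, c(7470, 36635, 46750, 59566, 78355, 250001))
  expect_equal(s$ProbNoInsurance$edges, c(0, 0.0637, 0.1121, 0.1644, 0.5548))
  expect_equal(s$AvgDailyPM25$edges, c(3.27, 6.30, 7.81, 10.83))
  expect_equal(s$MaxDailyOzone$edges, c(27.80, 39.00, 42.73, 46.45))
  expect_equal(s$RoadwayDistance$edges, c(0, 50, 100, 150, 200, 250, Inf))
})

test_that("scheme YAML round-trips", {
  s <- default_schemes()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schemes(s, path, identifiers = default_identifiers())
  s2 <- read_schemes(path)
  expect_equal(lapply(s2, unclass), lapply(s, unclass))
  expect_equal(attr(s2, "identifiers"), default_identifiers())
})

test_that("deidentify strips identifiers and re-bins every cell faithfully", {
  raw <- random_raw_frame(500)
  schemes <- default_schemes()
  ft <- deidentify(raw, schemes, identifiers = default_identifiers(),
                   study_year = 2016,
                   count_features = c("TotalEDInpatientVisits", "TotalPrednisoneRx"))
  # no identifier, geocode, date, or raw exposure column survives
  expect_true(assert_no_identifiers(ft))
  expect_false(any(c("patient_id", "birth_date", "x_m", "y_m") %in% names(ft$rows)))

  # cell-for-cell agreement with the independent re-binning oracle
  for (nm in c("ProbNoInsurance", "MedianIncome", "AvgDailyPM25",
               "MaxDailyOzone", "RoadwayDistance")) {
    s <- schemes[[nm]]
    oracle <- vapply(raw[[nm]], rebin_oracle, "",
                     edges = s$edges, labels = s$labels,
                     left_closed = s$closure == "left_closed")
    expect_equal(ft$rows[[nm]], unname(oracle), info = nm)
  }
  expect_equal(ft$rows$Sex, raw$Sex)
  expect_equal(ft$rows$TotalEDInpatientVisits, raw$TotalEDInpatientVisits)

  # a scheme naming an absent column is a configuration error
  bad <- schemes
  bad$Nope <- binning_scheme("Nope", "categorical_passthrough")
  expect_error(deidentify(raw, bad, default_identifiers(), 2016),
               class = "configuration_error")

  # empty input gives an empty table with the full schema
  empty <- deidentify(raw[0, ], schemes, default_identifiers(), 2016)
  expect_equal(nrow(empty$rows), 0)
  expect_true(all(vapply(schemes, `[[`, "", "feature") %in% names(empty$rows)))
})
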