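test_that("cohort definition filters rows like a brute-force scan", {
  ft <- tiny_table(200, seed = 3)
  all_rows <- define_cohort(ft, list())
  expect_equal(all_rows$size, 200)
  expect_match(all_rows$cohort_id, "^COHORT:[0-9a-f]{8}$")

  cons <- list(list(feature = "Color", operator = "=", value = "red"),
               list(feature = "Visits", operator = ">=", value = 1))
  ch <- define_cohort(ft, cons)
  brute <- sum(ft$rows$Color == "red" & ft$rows$Visits >= 1, na.rm = TRUE)
  expect_equal(ch$size, brute)
  # ordinal comparison uses bin position
  ch2 <- define_cohort(ft, list(list(feature = "Size", operator = "<=", value = "medium")))
  expect_equal(ch2$size, sum(ft$rows$Size %in% c("small", "medium")))
  # deterministic id for identical constraints
  expect_equal(define_cohort(ft, cons)$cohort_id, ch$cohort_id)
  # unknown labels and features are validation errors
  expect_error(define_cohort(ft, list(list(feature = "Size", operator = "=",
                                           value = "gigantic"))),
               class = "validation_error")
  expect_error(define_cohort(ft, list(list(feature = "Nope", operator = "=",
                                           value = "x"))),
               class = "lookup_error")
  # a constraint matched by no row gives a valid empty cohort
  ft$rows$Visits[] <- 0L
  expect_equal(define_cohort(ft, list(list(feature = "Visits", operator = ">",
                                           value = 5)))$size, 0)
})

test_that("contingency tables exclude missing rows and keep ordinal order", {
  rows <- data.frame(
    row_key = sprintf("R%d", 1:6),
    Size = c("small", "small", "large", "large", NA, "small"),
    Visits = c(0L, 2L, 0L, 1L, 1L, NA),
    stringsAsFactors = FALSE)
  ft <- feature_table(2016, list(
    list(name = "row_key", kind = "categorical", labels = character()),
    list(name = "Size", kind = "binned_ordinal", labels = c("small", "medium", "large")),
    list(name = "Visits", kind = "count", labels = character())), rows)
  outc <- outcome_feature("Visits", "=", 0)
  ct <- build_contingency(ft, NULL, outc, "Size")
  # hand count: rows 5 (missing Size) and 6 (missing Visits) excluded
  expect_equal(ct$n_excluded_missing, 2)
  expect_equal(ct$col_labels, c("small", "medium", "large"))
  expect_equal(ct$counts, rbind(c(1, 0, 1), c(1, 0, 1)))
  expect_error(build_contingency(ft, NULL, outc, "Visits"), class = "validation_error")

  # feature missing everywhere -> degenerate
  ft$rows$Size <- NA_character_
  expect_error(build_contingency(ft, NULL, outc, "Size"),
               class = "degenerate_table_error")
})

test_that("the Pearson statistic reproduces the published sex table and the oracle", {
  # published 2x2: females/males with vs without >= 1 annual ED/inpatient visit
  sex <- contingency_table(rbind(c(15587, 73944), c(10743, 57132)))
  res <- chi_square(sex)
  expect_equal(round(res$statistic, 1), 69.4)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)

  # proportional rows: exact independence
  indep <- chi_square(contingency_table(rbind(c(10, 20), c(30, 60))))
  expect_equal(indep$statistic, 0)
  expect_equal(indep$p_value, 1)

  # random tables agree with the direct-formula oracle
  set.seed(8)
  for (i in 1:50) {
    m <- random_table(sample(2:5, 1), sample(2:5, 1))
    got <- chi_square(contingency_table(m))
    want <- chisq_oracle(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
  }

  # invariant to row and column permutation
  m <- random_table(3, 4)
  base <- chi_square(contingency_table(m))$statistic
  perm <- chi_square(contingency_table(m[c(2, 1, 3), c(4, 1, 3, 2)]))$statistic
  expect_equal(perm, base, tolerance = 1e-12)

  # all-zero lines are pruned; df reflects the pruned table
  mz <- rbind(c(5, 0, 9), c(7, 0, 3))
  res <- chi_square(contingency_table(mz))
  expect_equal(res$df, 1)
  expect_true(res$pruned)
  expect_error(chi_square(contingency_table(rbind(c(3, 0), c(4, 0)))),
               class = "degenerate_table_error")
})

test_that("collapsing contiguous bins conserves totals and matches the summed oracle", {
  m <- random_table(2, 6, 400)
  ct <- contingency_table(m, col_labels = sprintf("b%d", 1:6))
  one <- collapse_bins(ct, list(1:6))
  expect_equal(drop(one$counts), rowSums(m))
  expect_error(collapse_bins(ct, list(c(1, 3), c(2, 4:6))), class = "validation_error")
  expect_error(collapse_bins(ct, list(1:2, 4:6)), class = "validation_error")

  set.seed(12)
  for (i in 1:20) {
    cuts <- sort(sample(1:5, sample(1:3, 1)))
    groups <- unname(split(1:6, findInterval(1:6, c(1, cuts + 1))))
    cl <- collapse_bins(ct, groups)
    # row marginals and grand total preserved
    expect_equal(rowSums(cl$counts), rowSums(m))
    summed <- vapply(groups, function(g) rowSums(m[, g, drop = FALSE]), numeric(2))
    expect_equal(cl$counts, matrix(summed, nrow = 2))
    expect_equal(chi_square(cl)$statistic, chisq_oracle(summed)$statistic,
                 tolerance = 1e-9)
  }
  expect_equal(collapse_bins(ct, list(1:3, 4:6))$col_labels, c("b1 - b3", "b4 - b6"))
})

test_that("the association battery corrects, sorts, skips and filters", {
  set.seed(21)
  n <- 400
  rows <- data.frame(row_key = sprintf("R%d", 1:n), stringsAsFactors = FALSE)
  schema <- list(list(name = "row_key", kind = "categorical", labels = character()))
  outcome_val <- rbinom(n, 1, 0.3)
  # one planted feature, 10 nulls, one constant (degenerate) feature
  rows$planted <- ifelse(runif(n) < plogis(-1 + 2 * outcome_val), "yes", "no")
  for (i in 1:10) rows[[sprintf("null%02d", i)]] <- sample(c("a", "b"), n, TRUE)
  rows$constant <- "same"
  rows$Outcome <- as.integer(outcome_val)
  schema <- c(schema,
              lapply(c("planted", sprintf("null%02d", 1:10)), function(nm)
                list(name = nm, kind = "categorical", labels = character())),
              list(list(name = "constant", kind = "categorical", labels = "same"),
                   list(name = "Outcome", kind = "count", labels = character())))
  ft <- feature_table(2016, schema, rows)
  outc <- outcome_feature("Outcome", "=", 0)
  bat <- associations_to_all_features(ft, NULL, outc, maximum_p_value = 1)

  # the constant feature is skipped and does not inflate m
  expect_true("constant" %in% names(bat$skipped))
  expect_equal(bat$m, 11)
  expect_equal(bat$alpha_adjusted, 0.05 / 11)
  # planted feature ranks first and is the only significant one
  expect_equal(bat$results[[1]]$feature, "planted")
  sig <- vapply(bat$results, `[[`, TRUE, "significant")
  expect_equal(names(sig)[sig], "planted")
  # sorted by p ascending
  ps <- vapply(bat$results, `[[`, 0, "p_value")
  expect_equal(ps, sort(ps))

  # Bonferroni significant set is a subset of the uncorrected one;
  # with no correction they coincide at the nominal threshold
  none <- associations_to_all_features(ft, NULL, outc, correction = "none")
  sig_none <- vapply(none$results, `[[`, TRUE, "significant")
  expect_true(all(names(sig)[sig] %in% names(sig_none)[sig_none]))
  expect_equal(unname(sig_none),
               unname(vapply(none$results, `[[`, 0, "p_value") < 0.05))

  # maximum_p_value filters the returned set
  expect_equal(length(associations_to_all_features(ft, NULL, outc,
                                                   maximum_p_value = 0)$results), 0)
  strict <- associations_to_all_features(ft, NULL, outc, maximum_p_value = 0.01)
  expect_true(all(vapply(strict$results, `[[`, 0, "p_value") <= 0.01))

  # tabular projection has one line per returned feature
  tab <- strsplit(format_tabular(bat), "\n")[[1]]
  expect_equal(length(tab), 1 + length(bat$results))
  expect_match(tab[1], "^feature\t")
})

test_that("a 50-comparison battery adjusts alpha to .001", {
  expect_equal(bonferroni_alpha(0.05, 50), 0.001)
})
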