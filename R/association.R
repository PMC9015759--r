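#' Define a cohort by feature constraints
#'
#' A cohort is the set of feature-table rows satisfying the conjunction
#' of constraints `(feature, operator, value)`. Operators `<, <=, >, >=`
#' compare ordinal bin position for binned features and numeric value for
#' count features; `=` matches labels or values exactly. Rows with a
#' missing value for a constrained feature never satisfy the constraint.
#' The cohort id is a stable hash of the canonicalized constraint set,
#' prefixed `COHORT:`.
#'
#' @param ft a [feature_table]
#' @param constraints list of `list(feature=, operator=, value=)`;
#'   an empty list selects every row
#' @return list with `cohort_id`, `constraints`, `size`, and the logical
#'   row `mask`
#' @export
define_cohort <- function(ft, constraints = list()) {
  mask <- rep(TRUE, nrow(ft$rows))
  for (con in constraints) {
    mask <- mask & apply_constraint(ft, con$feature, con$operator, con$value)
  }
  canon <- paste(vapply(constraints, function(con)
    paste(con$feature, con$operator, con$value, sep = "\x1f"), ""), collapse = "\x1e")
  id <- paste0("COHORT:", fnv1a(paste0(ft$study_year, "|", canon)))
  size <- sum(mask)
  if (size == 0L && length(constraints)) {
    log_msg("cohort is empty under the given constraints", level = "WARN")
  }
  list(cohort_id = id, constraints = constraints, size = size, mask = mask)
}

valid_operators <- c("=", "<", "<=", ">", ">=")

apply_constraint <- function(ft, feature, operator, value) {
  s <- feature_schema(ft, feature)
  assert_that(operator %in% valid_operators,
              sprintf("unknown operator '%s'", operator), "validation_error")
  v <- ft$rows[[feature]]
  if (s$kind == "count") {
    lhs <- as.numeric(v); rhs <- as.numeric(value)
  } else if (s$kind == "binned_ordinal") {
    lhs <- match(v, s$labels); rhs <- match(as.character(value), s$labels)
    if (is.na(rhs)) {
      abort(sprintf("label '%s' not in feature '%s'", value, feature),
            "validation_error")
    }
  } else {
    if (operator != "=") {
      abort(sprintf("operator '%s' invalid for categorical feature '%s'",
                    operator, feature), "validation_error")
    }
    lhs <- as.character(v); rhs <- as.character(value)
  }
  res <- switch(operator,
    "=" = lhs == rhs, "<" = lhs < rhs, "<=" = lhs <= rhs,
    ">" = lhs > rhs, ">=" = lhs >= rhs)
  res & !is.na(res)
}

#' Dichotomizing outcome feature
#'
#' Defines the two outcome groups for contingency tables: rows satisfying
#' `(operator, value)` on a count (or binned) feature versus the
#' complement. E.g. `outcome_feature("TotalEDInpatientVisits", "=", 0)`
#' splits patients into those with zero versus one-or-more annual
#' ED/inpatient visits.
#'
#' @param name feature name
#' @param operator one of `=, <, <=, >, >=`
#' @param value comparison value (count) or bin label
#' @return object of class `outcome_feature`
#' @export
outcome_feature <- function(name, operator = "=", value = 0) {
  assert_that(operator %in% valid_operators,
              sprintf("unknown operator '%s'", operator), "validation_error")
  structure(list(name = name, operator = operator, value = value),
            class = "outcome_feature")
}

outcome_labels <- function(outcome) {
  c(sprintf("%s %s %s", outcome$name, outcome$operator, outcome$value),
    sprintf("NOT(%s %s %s)", outcome$name, outcome$operator, outcome$value))
}

#' Build a contingency table of outcome dichotomy by feature bins
#'
#' Rows are the outcome dichotomy (constraint-true group first), columns
#' the feature's bins in ordinal order. Cohort rows with a missing
#' outcome or missing feature value are excluded from the table and
#' counted in `n_excluded_missing` (missing data are excluded from
#' analysis, not imputed).
#'
#' @param ft a [feature_table]
#' @param cohort a cohort from [define_cohort()] (or `NULL` for all rows)
#' @param outcome an [outcome_feature]
#' @param feature name of the feature to cross-tabulate
#' @return object of class `contingency_table`: `counts` (integer
#'   matrix), `row_labels`, `col_labels`, `feature`, `n_excluded_missing`
#' @export
build_contingency <- function(ft, cohort = NULL, outcome, feature) {
  assert_that(feature != outcome$name, "feature equals the outcome source feature",
              "validation_error")
  s <- feature_schema(ft, feature)
  mask <- if (is.null(cohort)) rep(TRUE, nrow(ft$rows)) else cohort$mask
  fv <- ft$rows[[feature]][mask]
  ov <- ft$rows[[outcome$name]][mask]
  keep <- !is.na(fv) & !is.na(ov)
  n_excl <- sum(!keep)
  fv <- fv[keep]
  grp <- apply_constraint(ft, outcome$name, outcome$operator, outcome$value)[mask][keep]

  labels <- if (s$kind == "count") as.character(sort(unique(as.integer(fv))))
            else if (length(s$labels)) s$labels
            else sort(unique(as.character(fv)))
  if (!length(fv) || all(grp) || !any(grp)) {
    abort(sprintf("degenerate table for '%s': an outcome group is empty", feature),
          "degenerate_table_error")
  }
  col <- factor(as.character(fv), levels = labels)
  row <- factor(ifelse(grp, "g1", "g2"), levels = c("g1", "g2"))
  counts <- unclass(table(row, col))
  dimnames(counts) <- NULL
  structure(list(counts = counts,
                 row_labels = outcome_labels(outcome),
                 col_labels = labels,
                 feature = feature,
                 n_excluded_missing = n_excl),
            class = "contingency_table")
}

#' Construct a contingency table from a count matrix
#'
#' @param counts non-negative integer matrix (rows = outcome groups,
#'   columns = feature bins in ordinal order)
#' @param row_labels,col_labels dimension labels
#' @param feature feature name
#' @param n_excluded_missing rows excluded for missing data
#' @return a `contingency_table`
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL,
                              feature = "feature", n_excluded_missing = 0L) {
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0) && all(counts %% 1 == 0),
              "counts must be non-negative integers")
  structure(list(counts = counts,
                 row_labels = row_labels %||% paste0("row", seq_len(nrow(counts))),
                 col_labels = col_labels %||% paste0("bin", seq_len(ncol(counts))),
                 feature = feature,
                 n_excluded_missing = as.integer(n_excluded_missing)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- x$counts
  dimnames(m) <- list(x$row_labels, x$col_labels)
  cat(sprintf("<contingency_table> feature=%s, %d excluded for missing data\n",
              x$feature, x$n_excluded_missing))
  print(m)
  invisible(x)
}

prune_zero_lines <- function(counts) {
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  pruned <- !all(keep_r) || !all(keep_c)
  if (pruned) log_msg("all-zero row(s)/column(s) pruned before chi-square")
  list(counts = counts[keep_r, keep_c, drop = FALSE], pruned = pruned,
       keep_r = keep_r, keep_c = keep_c)
}

#' Pearson chi-square test of a contingency table
#'
#' The Pearson statistic `sum((O - E)^2 / E)` with expected counts from
#' the row/column marginals, no continuity correction (also for 2x2
#' tables), degrees of freedom `(r - 1)(c - 1)` after pruning all-zero
#' rows and columns, and the p-value from the upper tail of the
#' chi-square distribution.
#'
#' @param ct a `contingency_table` or plain count matrix
#' @return list `statistic`, `df`, `p_value`, plus `pruned` flag
#' @export
chi_square <- function(ct) {
  counts <- if (inherits(ct, "contingency_table")) ct$counts else as.matrix(ct)
  pr <- prune_zero_lines(counts)
  counts <- pr$counts
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("need >= 2 non-zero rows and columns for chi-square",
          "degenerate_table_error")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), pruned = pr$pruned)
}

#' Collapse contiguous bins of a contingency table
#'
#' Sums column counts within each group of a partition of the columns
#' into runs of adjacent indices; labels are joined with `" - "`. Row
#' sums (and hence the grand total) are preserved. Non-contiguous or
#' non-partition groupings are rejected.
#'
#' @param ct a `contingency_table`
#' @param groups list of integer vectors, an ordered partition of
#'   `1:ncol` into contiguous runs
#' @return a collapsed `contingency_table`
#' @export
collapse_bins <- function(ct, groups) {
  assert_that(inherits(ct, "contingency_table"), "ct must be a contingency_table")
  idx <- unlist(groups, use.names = FALSE)
  if (!identical(as.integer(idx), seq_len(ncol(ct$counts)))) {
    abort("groups must partition columns into runs of adjacent indices",
          "validation_error")
  }
  for (g in groups) {
    g <- as.integer(g)
    if (length(g) > 1 && !all(diff(g) == 1L)) {
      abort("non-contiguous bin group", "validation_error")
    }
  }
  counts <- vapply(groups, function(g) rowSums(ct$counts[, g, drop = FALSE]),
                   numeric(nrow(ct$counts)))
  counts <- matrix(counts, nrow = nrow(ct$counts))
  labels <- vapply(groups, function(g) {
    if (length(g) == 1) ct$col_labels[g]
    else paste(ct$col_labels[g[1]], ct$col_labels[g[length(g)]], sep = " - ")
  }, "")
  contingency_table(counts, row_labels = ct$row_labels, col_labels = labels,
                    feature = ct$feature, n_excluded_missing = ct$n_excluded_missing)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise significance level
#' @param m number of comparisons actually tested
#' @return `alpha / m`
#' @export
bonferroni_alpha <- function(alpha, m) {
  assert_that(is_probability(alpha), "alpha must be in [0, 1]")
  assert_that(m >= 1, "m must be >= 1")
  alpha / m
}

#' Chi-square association battery: one outcome against all features
#'
#' For every eligible feature (everything in the table except the
#' outcome's source feature and the row key), builds the outcome-by-bins
#' contingency table on the cohort, runs the Pearson chi-square test, and
#' applies a multiple-comparison correction with `m` equal to the number
#' of features that produced a valid test (degenerate features — all
#' missing, constant, or one-sided — are skipped with a recorded reason
#' and do not inflate the correction). Results with `p <= maximum_p_value`
#' are returned sorted by p ascending, ties broken by feature name.
#'
#' @param ft a [feature_table]
#' @param cohort a cohort from [define_cohort()], or `NULL` for all rows
#' @param outcome an [outcome_feature]
#' @param maximum_p_value report only results with p at or below this
#' @param alpha family-wise significance level
#' @param correction `"bonferroni"` or `"none"`
#' @param features optional subset of feature names to test
#' @return object of class `association_battery`: list with `results`
#'   (list of per-feature results), `skipped`, `m`, `alpha`,
#'   `alpha_adjusted`, `outcome`, `cohort_id`
#' @export
associations_to_all_features <- function(ft, cohort = NULL, outcome,
                                         maximum_p_value = 1,
                                         alpha = 0.05,
                                         correction = c("bonferroni", "none"),
                                         features = NULL) {
  correction <- match.arg(correction)
  assert_that(is_probability(maximum_p_value), "maximum_p_value must be in [0, 1]")
  feats <- features %||% setdiff(feature_names(ft), c("row_key", outcome$name))
  results <- list(); skipped <- list()
  for (f in feats) {
    res <- tryCatch({
      ct <- build_contingency(ft, cohort, outcome, f)
      test <- withCallingHandlers(chi_square(ct),
                                  warning = function(w) invokeRestart("muffleWarning"))
      pct <- sweep(ct$counts, 2, colSums(ct$counts), "/") * 100
      list(feature = f, table = ct, chi_square = test$statistic, df = test$df,
           p_value = test$p_value, percent = pct)
    }, opencohort_error = function(e) e)
    if (inherits(res, "opencohort_error")) {
      skipped[[f]] <- conditionMessage(res)
      log_msg(sprintf("feature '%s' skipped: %s", f, conditionMessage(res)))
    } else {
      results[[f]] <- res
    }
  }
  m <- length(results)
  alpha_adjusted <- if (correction == "bonferroni" && m > 0) {
    bonferroni_alpha(alpha, m)
  } else {
    alpha
  }
  for (f in names(results)) {
    results[[f]]$alpha_adjusted <- alpha_adjusted
    results[[f]]$significant <- results[[f]]$p_value < alpha_adjusted
  }
  ord <- order(vapply(results, `[[`, 0, "p_value"),
               vapply(results, `[[`, "", "feature"))
  results <- results[ord]
  keep <- vapply(results, function(r) r$p_value <= maximum_p_value, TRUE)
  structure(list(results = results[keep], skipped = skipped, m = m,
                 alpha = alpha, alpha_adjusted = alpha_adjusted,
                 correction = correction, outcome = outcome,
                 cohort_id = if (!is.null(cohort)) cohort$cohort_id else "COHORT:all"),
            class = "association_battery")
}

#' Flatten an association battery to a data.frame
#'
#' One row per tested feature: bins, semicolon-joined counts per outcome
#' group, per-bin percentages of the constraint-complement group, the
#' chi-square statistic, df, p-value, adjusted threshold and significance
#' flag — the tabular representation of the association API.
#'
#' @param x an `association_battery`
#' @param ... unused
#' @return data.frame
#' @export
as.data.frame.association_battery <- function(x, ...) {
  if (!length(x$results)) {
    return(data.frame(feature = character(), bins = character(),
                      counts_group1 = character(), counts_group2 = character(),
                      percent_group2 = character(), chi_square = numeric(),
                      df = integer(), p_value = numeric(),
                      alpha_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(
      feature = r$feature,
      bins = paste(r$table$col_labels, collapse = ";"),
      counts_group1 = paste(r$table$counts[1, ], collapse = ";"),
      counts_group2 = paste(r$table$counts[2, ], collapse = ";"),
      percent_group2 = paste(round_half_up(r$percent[2, ], 2), collapse = ";"),
      chi_square = r$chi_square, df = r$df, p_value = r$p_value,
      alpha_adjusted = r$alpha_adjusted, significant = r$significant,
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Render an association battery as a text/tabular body
#'
#' @param x an `association_battery`
#' @return a single tab-separated string (header + one line per feature)
#' @export
format_tabular <- function(x) {
  df <- as.data.frame(x)
  lines <- c(paste(names(df), collapse = "\t"),
             vapply(seq_len(nrow(df)), function(i)
               paste(vapply(df[i, ], as.character, ""), collapse = "\t"), ""))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.association_battery <- function(x, ...) {
  cat(sprintf("<association_battery> outcome: %s %s %s | m=%d tested, alpha_adjusted=%g\n",
              x$outcome$name, x$outcome$operator, x$outcome$value,
              x$m, x$alpha_adjusted))
  df <- as.data.frame(x)
  if (nrow(df)) {
    print(df[, c("feature", "chi_square", "df", "p_value", "significant")],
          row.names = FALSE)
  }
  if (length(x$skipped)) {
    cat("skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}
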