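#' Binning schemes for de-identification
#'
#' A binning scheme maps a continuous or identifying feature onto a small
#' ordered set of labelled bins, which is the only representation the open
#' feature table exposes. Four strategies are supported:
#'
#' * `explicit_edges` — fixed numeric edges shipped with the package or
#'   supplied by the user (the authoritative strategy for the default
#'   exposure and socioeconomic schemes);
#' * `frequency_quantiles` — edges at empirical quantiles so bins hold
#'   near-equal counts;
#' * `value_cut` — `k` equal-width intervals spanning the observed range;
#' * `categorical_passthrough` — categories kept as-is (optionally
#'   collapsed).
#'
#' Interval closure follows the convention used in the shipped schemes:
#' with `closure = "first_closed"` the first interval is closed on both
#' ends and subsequent intervals are left-open/right-closed, e.g.
#' `[3.27, 6.30], (6.30, 7.81]`. With `closure = "left_closed"` all
#' intervals are `[a, b)` (used for the integer roadway-distance bins
#' `0-49, 50-99, ..., >=250`, where the last edge may be `Inf`).
#'
#' @param feature name of the column the scheme applies to
#' @param strategy one of `"explicit_edges"`, `"frequency_quantiles"`,
#'   `"value_cut"`, `"categorical_passthrough"`
#' @param edges strictly increasing numeric edges (explicit/value
#'   strategies); last edge may be `Inf`
#' @param k number of bins (frequency/value strategies)
#' @param closure `"first_closed"` or `"left_closed"`
#' @param labels optional character labels, one per interval
#' @param levels for categorical passthrough, the allowed categories (in
#'   display order); `NULL` accepts any observed category
#' @return an object of class `binning_scheme`
#' @export
binning_scheme <- function(feature, strategy,
                           edges = NULL, k = NULL,
                           closure = c("first_closed", "left_closed"),
                           labels = NULL, levels = NULL) {
  closure <- match.arg(closure)
  strategy <- match.arg(strategy, c("explicit_edges", "frequency_quantiles",
                                    "value_cut", "categorical_passthrough"))
  if (strategy == "explicit_edges") {
    assert_that(is.numeric(edges) && length(edges) >= 2, "edges must be numeric, length >= 2")
    assert_that(all(diff(edges) > 0), "edges must be strictly increasing")
  }
  if (strategy %in% c("frequency_quantiles", "value_cut")) {
    assert_that(!is.null(k) && k >= 2, "k must be >= 2", "configuration_error")
  }
  if (!is.null(edges) && !is.null(labels)) {
    assert_that(length(labels) == length(edges) - 1L,
                "labels count must equal interval count")
  }
  if (is.null(labels) && !is.null(edges)) labels <- interval_labels(edges, closure)
  structure(list(feature = feature, strategy = strategy, edges = edges, k = k,
                 closure = closure, labels = labels, levels = levels),
            class = "binning_scheme")
}

interval_labels <- function(edges, closure) {
  m <- length(edges) - 1L
  labs <- character(m)
  for (i in seq_len(m)) {
    a <- edges[i]; b <- edges[i + 1]
    labs[i] <- if (closure == "left_closed") {
      if (is.infinite(b)) sprintf(">=%s", format(a)) else sprintf("[%s, %s)", format(a), format(b))
    } else {
      open <- if (i == 1L) "[" else "("
      sprintf("%s%s, %s]", open, format(a), format(b))
    }
  }
  labs
}

#' Assign values to the bins of an explicit-edge scheme
#'
#' Values outside the scheme's span (below the first edge, or above the
#' last edge for bounded schemes) map to missing with a warning; missing
#' or non-numeric input maps to missing silently.
#'
#' @param values numeric vector
#' @param scheme a `binning_scheme` with numeric edges
#' @return character vector of bin labels (`NA` for out-of-range/missing);
#'   attribute `"index"` carries the 0-based ordinal bin index
#' @export
apply_explicit <- function(values, scheme) {
  assert_that(inherits(scheme, "binning_scheme"), "scheme must be a binning_scheme")
  assert_that(!is.null(scheme$edges), "scheme has no edges", "configuration_error")
  values <- suppressWarnings(as.numeric(values))
  right <- scheme$closure == "first_closed"
  idx <- as.integer(cut(values, breaks = scheme$edges,
                        right = right, include.lowest = right))
  oob <- !is.na(values) & is.na(idx)
  if (any(oob)) {
    warning(sprintf("%d value(s) outside the bin range of '%s' set to missing",
                    sum(oob), scheme$feature))
  }
  out <- scheme$labels[idx]
  attr(out, "index") <- idx - 1L
  out
}

#' Age binning with the HIPAA top-code
#'
#' Age is computed in completed years on January 1 of the study year and
#' mapped to the bins `<5`, `5-17`, `18-44`, `45-64`, `65-89`. Ages above
#' 89 (the oldest permissible age under HIPAA Safe Harbor) are excluded:
#' the label is `NA` and the logical attribute `"excluded"` flags the row,
#' unless `cap_to_top = TRUE`, in which case they fall in `65-89`.
#'
#' @param birth_date `Date` vector (or coercible)
#' @param study_year integer calendar year; the reference date is Jan 1
#' @param cap_to_top cap ages > 89 into the top bin instead of excluding
#' @return character labels with attributes `"index"` and `"excluded"`
#' @export
bin_age <- function(birth_date, study_year, cap_to_top = FALSE) {
  birth_date <- as.Date(birth_date)
  ref <- as.Date(sprintf("%d-01-01", study_year))
  bad <- !is.na(birth_date) & birth_date > ref
  if (any(bad)) abort("birth_date after the study reference date", "validation_error")
  by <- as.integer(format(birth_date, "%Y"))
  not_jan1 <- format(birth_date, "%m-%d") != "01-01"
  age <- study_year - by - as.integer(not_jan1)
  labels <- c("<5", "5-17", "18-44", "45-64", "65-89")
  idx <- as.integer(cut(age, breaks = c(0, 5, 18, 45, 65, 90), right = FALSE))
  excluded <- !is.na(age) & age > 89
  if (cap_to_top) {
    idx[excluded] <- 5L
    excluded <- excluded & FALSE
  } else {
    idx[excluded] <- NA_integer_
  }
  out <- labels[idx]
  attr(out, "index") <- idx - 1L
  attr(out, "excluded") <- excluded
  attr(out, "age") <- age
  out
}

#' Fit a frequency (quantile) binning scheme
#'
#' Edges are placed at the 0, 1/k, ..., 1 empirical quantiles using linear
#' interpolation between order statistics (`stats::quantile` type 7, the
#' same definition used by common frequency-binning tools). Duplicate
#' edges arising from heavy ties are merged with a warning, reducing the
#' bin count.
#'
#' @param values numeric vector (missing values dropped)
#' @param k requested number of bins
#' @param feature feature name recorded in the scheme
#' @return a `binning_scheme` with strategy `explicit_edges` and
#'   first-closed closure
#' @export
fit_frequency_quantiles <- function(values, k, feature = "feature") {
  v <- values[is.finite(values)]
  if (length(unique(v)) < k) {
    abort(sprintf("need at least k=%d distinct finite values, have %d",
                  k, length(unique(v))), "degenerate_input_error")
  }
  edges <- unname(stats::quantile(v, probs = seq(0, 1, length.out = k + 1), type = 7))
  if (anyDuplicated(edges)) {
    warning("duplicate quantile edges merged; bin count reduced")
    edges <- unique(edges)
  }
  if (length(edges) < 3) abort("degenerate quantile edges", "degenerate_input_error")
  binning_scheme(feature, "explicit_edges", edges = edges, closure = "first_closed")
}

#' Fit an equal-width (value cut) binning scheme
#'
#' `k` equal-width intervals spanning `[min, max]` of the observed values;
#' the first interval is closed on both ends.
#'
#' @inheritParams fit_frequency_quantiles
#' @return a `binning_scheme`
#' @export
fit_value_cut <- function(values, k, feature = "feature") {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2) {
    abort("value_cut needs at least 2 distinct finite values", "degenerate_input_error")
  }
  edges <- seq(min(v), max(v), length.out = k + 1)
  binning_scheme(feature, "explicit_edges", edges = edges, closure = "first_closed")
}

apply_scheme <- function(values, scheme) {
  switch(scheme$strategy,
    explicit_edges = apply_explicit(values, scheme),
    categorical_passthrough = {
      out <- as.character(values)
      out[!nzchar(out) | is.na(out)] <- NA_character_
      if (!is.null(scheme$levels)) {
        unknown <- !is.na(out) & !(out %in% scheme$levels)
        if (any(unknown)) {
          warning(sprintf("%d value(s) outside the category set of '%s' set to missing",
                          sum(unknown), scheme$feature))
          out[unknown] <- NA_character_
        }
      }
      out
    },
    frequency_quantiles = apply_explicit(values, fit_frequency_quantiles(values, scheme$k, scheme$feature)),
    value_cut = apply_explicit(values, fit_value_cut(values, scheme$k, scheme$feature))
  )
}

scheme_labels <- function(scheme, observed = character()) {
  if (scheme$strategy == "categorical_passthrough") {
    scheme$levels %||% sort(unique(observed[!is.na(observed)]))
  } else {
    scheme$labels
  }
}

#' Default binning schemes for the shipped feature set
#'
#' The explicit edges encode the study's published binning of the
#' socioeconomic and airborne-pollutant exposures: income quintiles
#' 7,470 / 36,635 / 46,750 / 59,566 / 78,355 / 250,001 US$; probability of
#' no health insurance quartiles 0 / 0.0637 / 0.1121 / 0.1644 / 0.5548;
#' annual mean PM2.5 3.27 / 6.30 / 7.81 / 10.83 ug/m3; annual mean of
#' daily-maximum ozone 27.80 / 39.00 / 42.73 / 46.45 ppb; roadway distance
#' 0-49 / 50-99 / 100-149 / 150-199 / 200-249 / >=250 m. Sex, race,
#' ethnicity and residential density pass through as categories.
#'
#' @param path optional YAML scheme file; defaults to the file shipped in
#'   `inst/extdata/default_schemes.yaml`
#' @return named list of `binning_scheme` objects
#' @export
default_schemes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "default_schemes.yaml",
                                package = "opencohort", mustWork = TRUE)
  read_schemes(path)
}

#' Read / write binning schemes as YAML
#'
#' @param path YAML file path
#' @return `read_schemes`: named list of `binning_scheme`;
#'   `write_schemes`: the path, invisibly
#' @export
read_schemes <- function(path) {
  raw <- yaml::read_yaml(path)
  schemes <- lapply(raw$schemes, function(s) {
    binning_scheme(
      feature = s$feature, strategy = s$strategy,
      edges = if (!is.null(s$edges)) unname(vapply(s$edges, function(e) {
        if (identical(e, ".inf") || identical(e, "Inf")) Inf else as.numeric(e)
      }, numeric(1))),
      k = s$k, closure = s$closure %||% "first_closed",
      labels = if (!is.null(s$labels)) as.character(s$labels),
      levels = if (!is.null(s$levels)) as.character(s$levels)
    )
  })
  names(schemes) <- vapply(schemes, `[[`, "", "feature")
  attr(schemes, "identifiers") <- as.character(raw$identifiers %||% character())
  schemes
}

#' @rdname read_schemes
#' @param schemes named list of `binning_scheme`
#' @param identifiers identifier drop-list stored alongside the schemes
#' @export
write_schemes <- function(schemes, path, identifiers = attr(schemes, "identifiers")) {
  out <- list(
    identifiers = as.list(identifiers %||% character()),
    schemes = lapply(schemes, function(s) {
      Filter(Negate(is.null), list(
        feature = s$feature, strategy = s$strategy,
        edges = if (!is.null(s$edges)) {
          lapply(unname(as.list(s$edges)),
                 function(e) if (is.infinite(e)) "Inf" else e)
        },
        k = s$k, closure = s$closure,
        labels = if (!is.null(s$labels)) as.list(s$labels),
        levels = if (!is.null(s$levels)) as.list(s$levels)
      ))
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' De-identify a raw patient-level frame into a feature table
#'
#' Applies one binning scheme per configured feature, drops every column
#' on the identifier list (and any raw column that fed a scheme), and
#' returns a [feature_table] containing only binned / categorical /
#' small-count columns plus the study year and an opaque row key. This is
#' the Safe-Harbor step: geocodes, dates and raw exposure estimates never
#' appear in the output.
#'
#' @param raw data.frame of one row per patient; must contain every
#'   scheme's feature column
#' @param schemes named list of `binning_scheme`
#' @param identifiers character vector of identifier column names to drop
#' @param study_year integer study year recorded on the table
#' @param count_features names of raw columns kept as small non-negative
#'   counts (e.g. annual outcome tallies)
#' @param age_column,birth_column if `birth_column` is present, age is
#'   binned from the birth date via [bin_age()] into `age_column`; rows
#'   with age > 89 are dropped (Safe Harbor top-code) unless
#'   `cap_age_to_top`
#' @param cap_age_to_top see [bin_age()]
#' @return a [feature_table]
#' @export
deidentify <- function(raw, schemes, identifiers,
                       study_year,
                       count_features = character(),
                       age_column = "AgeStudyStart",
                       birth_column = "birth_date",
                       cap_age_to_top = FALSE) {
  assert_that(is.data.frame(raw), "raw must be a data.frame")
  missing_cols <- setdiff(vapply(schemes, `[[`, "", "feature"), names(raw))
  if (length(missing_cols)) {
    abort(sprintf("scheme(s) reference absent column(s): %s",
                  paste(missing_cols, collapse = ", ")), "configuration_error")
  }
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  n_excluded_age <- 0L
  age_labels <- NULL
  if (birth_column %in% names(raw)) {
    ab <- bin_age(raw[[birth_column]], study_year, cap_to_top = cap_age_to_top)
    excl <- attr(ab, "excluded")
    if (any(excl)) {
      n_excluded_age <- sum(excl)
      log_msg(sprintf("%d row(s) excluded: age > 89", n_excluded_age), level = "WARN")
      keep <- !excl
      raw <- raw[keep, , drop = FALSE]
      ab <- ab[keep]
    }
    age_labels <- as.character(ab)
  }

  n <- nrow(raw)
  cols <- list(row_key = sprintf("R%06d", seq_len(n)))
  schema <- list(list(name = "row_key", kind = "categorical", labels = character()))
  if (!is.null(age_labels)) {
    cols[[age_column]] <- age_labels
    schema[[length(schema) + 1L]] <- list(name = age_column, kind = "binned_ordinal",
                                          labels = c("<5", "5-17", "18-44", "45-64", "65-89"))
  }
  for (s in schemes) {
    vals <- apply_scheme(raw[[s$feature]], s)
    cols[[s$feature]] <- as.character(vals)
    schema[[length(schema) + 1L]] <- list(
      name = s$feature,
      kind = if (s$strategy == "categorical_passthrough") "categorical" else "binned_ordinal",
      labels = scheme_labels(s, raw[[s$feature]])
    )
  }
  for (cf in count_features) {
    assert_that(cf %in% names(raw), sprintf("count feature '%s' absent", cf),
                "configuration_error")
    v <- as.integer(raw[[cf]])
    assert_that(all(is.na(v) | v >= 0), sprintf("count feature '%s' negative", cf))
    cols[[cf]] <- v
    schema[[length(schema) + 1L]] <- list(name = cf, kind = "count", labels = character())
  }
  rows <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  ft <- feature_table(study_year = study_year, schema = schema, rows = rows,
                      provenance = list(n_excluded_age = n_excluded_age,
                                        identifiers_dropped = identifiers))
  assert_no_identifiers(ft, identifiers)
  ft
}

#' Assert that no identifier column survived
#'
#' Schema-level privacy check: errors if any column of a feature table,
#' data.frame, or API response payload matches the identifier drop-list.
#'
#' @param x a `feature_table`, data.frame, or character vector of names
#' @param identifiers identifier column names (defaults to the shipped
#'   drop-list)
#' @return `TRUE` invisibly
#' @export
assert_no_identifiers <- function(x, identifiers = default_identifiers()) {
  nms <- if (inherits(x, "feature_table")) names(x$rows)
         else if (is.data.frame(x)) names(x)
         else as.character(x)
  hit <- intersect(tolower(nms), tolower(identifiers))
  if (length(hit)) {
    abort(sprintf("identifier column(s) present in output: %s",
                  paste(hit, collapse = ", ")), "privacy_error")
  }
  invisible(TRUE)
}

#' Shipped identifier drop-list
#'
#' Columns that must never appear in an exposed feature table or API
#' response: direct identifiers, geocodes, dates, and raw (unbinned)
#' exposure estimates, which are treated as secondary protected health
#' information because they derive from geocodes and dates.
#'
#' @return character vector of column names
#' @export
default_identifiers <- function() {
  c("patient_id", "birth_date", "date", "x_m", "y_m", "geocode",
    "blockgroup_id", "raw_pm25", "raw_ozone", "raw_roadway_distance",
    "raw_median_income", "raw_prob_no_insurance")
}
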