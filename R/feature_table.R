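#' Integrated feature table
#'
#' The openly exposable unit: one row per patient per study year, cells
#' holding only bin labels, categories, or small counts — never raw
#' values, geocodes, or dates. Missing values are explicit (`NA`
#' internally, empty string on disk).
#'
#' @param study_year integer calendar year the table refers to
#' @param schema list of `list(name, kind, labels)` entries, `kind` one of
#'   `binned_ordinal`, `categorical`, `count`; `labels` gives the ordinal
#'   order for binned features
#' @param rows data.frame with one column per schema entry
#' @param provenance free-form list recorded in the sidecar (scheme
#'   provenance, exclusion tallies)
#' @return object of class `feature_table`
#' @export
feature_table <- function(study_year, schema, rows, provenance = list()) {
  nms <- vapply(schema, `[[`, "", "name")
  assert_that(identical(sort(nms), sort(names(rows))),
              "schema and row columns disagree", "format_error")
  rows <- rows[, nms, drop = FALSE]
  validate_cells(schema, rows)
  structure(list(study_year = as.integer(study_year), schema = schema,
                 rows = rows, provenance = provenance),
            class = "feature_table")
}

validate_cells <- function(schema, rows) {
  for (s in schema) {
    v <- rows[[s$name]]
    if (s$kind == "count") {
      bad <- which(!is.na(v) & (suppressWarnings(as.numeric(v)) < 0 |
                                suppressWarnings(as.numeric(v)) %% 1 != 0))
      if (length(bad)) {
        abort(sprintf("feature '%s': invalid count at row %d", s$name, bad[1]),
              "format_error")
      }
    } else if (length(s$labels)) {
      bad <- which(!is.na(v) & !(v %in% s$labels))
      if (length(bad)) {
        abort(sprintf("feature '%s': label '%s' at row %d not in schema",
                      s$name, v[bad[1]], bad[1]), "format_error")
      }
    }
  }
  invisible(TRUE)
}

feature_names <- function(ft) vapply(ft$schema, `[[`, "", "name")

feature_schema <- function(ft, feature) {
  i <- match(feature, feature_names(ft))
  if (is.na(i)) abort(sprintf("unknown feature '%s'", feature), "lookup_error")
  ft$schema[[i]]
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> study_year=%d, %d rows, %d features\n",
              x$study_year, nrow(x$rows), length(x$schema) - 1L))
  cat("features:", paste(setdiff(feature_names(x), "row_key"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$rows)

#' Write / read a feature table
#'
#' The table is written as a plain CSV (missing cells as empty strings)
#' plus a JSON sidecar `<path>.meta.json` carrying the study year, the
#' ordered schema with bin labels, and scheme provenance, so that
#' `read_feature_table(write_feature_table(ft, p))` round-trips exactly.
#' On read, every cell is validated against the schema; a cell whose label
#' is not in its feature's label set raises a format error naming the row.
#'
#' @param ft a [feature_table]
#' @param path CSV path; the sidecar is written next to it
#' @return `write_feature_table`: `path` invisibly; `read_feature_table`:
#'   a [feature_table]
#' @export
write_feature_table <- function(ft, path) {
  assert_that(inherits(ft, "feature_table"), "not a feature_table")
  dt <- data.table::as.data.table(ft$rows)
  data.table::fwrite(dt, path, na = "", quote = TRUE)
  meta <- list(study_year = ft$study_year, schema = ft$schema,
               provenance = ft$provenance,
               missing_sentinel = "")
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  assert_that(file.exists(path) && file.exists(meta_path),
              "feature table CSV or sidecar missing", "format_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  schema <- lapply(meta$schema, function(s) {
    list(name = s$name, kind = s$kind, labels = unlist(s$labels) %||% character())
  })
  nms <- vapply(schema, `[[`, "", "name")
  kinds <- vapply(schema, `[[`, "", "kind")
  classes <- ifelse(kinds == "count", "integer", "character")
  rows <- data.table::fread(path, colClasses = stats::setNames(classes, nms),
                            na.strings = "", data.table = FALSE)
  for (j in which(classes == "character")) {
    v <- rows[[nms[j]]]
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    rows[[nms[j]]] <- v
  }
  feature_table(meta$study_year, schema, rows,
                provenance = meta$provenance %||% list())
}

#' Tabulate one feature of a feature table
#'
#' Counts and percentages per label, with missing reported as its own row
#' and percentages computed over the total row count (missing included in
#' the denominator, the convention of cohort characteristic tables).
#' Percentages are rounded half-up to 2 decimals.
#'
#' @param ft a [feature_table]
#' @param feature feature name
#' @return data.frame with columns `label`, `n`, `pct`
#' @export
tabulate_feature <- function(ft, feature) {
  s <- feature_schema(ft, feature)
  v <- ft$rows[[feature]]
  total <- length(v)
  labels <- if (s$kind == "count") as.character(sort(unique(v[!is.na(v)])))
            else if (length(s$labels)) s$labels
            else sort(unique(v[!is.na(v)]))
  counts <- vapply(labels, function(l) sum(!is.na(v) & as.character(v) == l), 0L)
  out <- data.frame(label = c(labels, "Missing"),
                    n = c(counts, sum(is.na(v))),
                    stringsAsFactors = FALSE)
  out$pct <- round_half_up(100 * out$n / total, 2)
  stopifnot(sum(out$n) == total)
  out
}

#' Summarize every feature of a table
#'
#' A cohort-characteristics style report: per-feature label counts and
#' percentages including missing.
#'
#' @param ft a [feature_table]
#' @return data.frame with columns `feature`, `label`, `n`, `pct`
#' @export
summarize_table <- function(ft) {
  feats <- setdiff(feature_names(ft), "row_key")
  do.call(rbind, lapply(feats, function(f) {
    tab <- tabulate_feature(ft, f)
    cbind(feature = f, tab, stringsAsFactors = FALSE)
  }))
}
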