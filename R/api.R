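#' Feature-table registry for the query service
#'
#' A registry maps study years to feature tables and holds the cohorts
#' defined against them. Registering a table also defines the
#' all-patients cohort for that year and returns its id.
#'
#' @return an empty registry (environment of class `table_registry`)
#' @export
table_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$tables <- list()
  reg$cohorts <- list()
  class(reg) <- "table_registry"
  reg
}

#' @rdname table_registry
#' @param reg a registry
#' @param ft a [feature_table]
#' @return `register_table`: the id of the all-rows cohort, invisibly
#' @export
register_table <- function(reg, ft) {
  year <- as.character(ft$study_year)
  reg$tables[[year]] <- ft
  all_cohort <- define_cohort(ft, list())
  reg$cohorts[[year]] <- c(reg$cohorts[[year]] %||% list(),
                           stats::setNames(list(all_cohort), all_cohort$cohort_id))
  invisible(all_cohort$cohort_id)
}

api_error <- function(status, reason) {
  list(status = status, content_type = "application/json",
       body = jsonlite::toJSON(list(error = reason), auto_unbox = TRUE))
}

parse_constraints <- function(feature_obj) {
  lapply(names(feature_obj), function(nm) {
    spec <- feature_obj[[nm]]
    list(feature = nm, operator = spec$operator, value = spec$value)
  })
}

#' Handle one API request
#'
#' The pure request handler behind [serve_api()]. Routes:
#'
#' * `GET /apispec` — machine-readable interface description;
#' * `POST /patient/{year}/cohort` — define a cohort from a JSON body
#'   `{"feature": {name: {"operator": op, "value": v}}}`; returns
#'   `cohort_id` and `size`;
#' * `GET /patient/{year}/cohort/{id}` — cohort definition;
#' * `POST /patient/{year}/cohort/{id}/associations_to_all_features` —
#'   body `{"feature": {outcome constraint}, "maximum_p_value": q}`; runs
#'   the chi-square battery. With `Accept: text/tabular` the body is the
#'   tabular projection, otherwise JSON.
#'
#' Responses never contain identifier columns; unknown years or cohorts
#' give 404, malformed bodies 400.
#'
#' @param reg a [table_registry()]
#' @param method HTTP method
#' @param path request path
#' @param body raw request body (JSON string or `NULL`)
#' @param accept the Accept header value
#' @return list with `status`, `content_type`, `body`
#' @export
handle_request <- function(reg, method, path, body = NULL, accept = "application/json") {
  path <- sub("\\?.*$", "", path)
  parts <- strsplit(sub("^/", "", utils::URLdecode(path)), "/", fixed = TRUE)[[1]]

  if (method == "GET" && identical(parts, "apispec")) {
    return(list(status = 200L, content_type = "application/json",
                body = jsonlite::toJSON(api_description(reg), auto_unbox = TRUE,
                                        pretty = TRUE)))
  }
  if (length(parts) >= 3 && parts[1] == "patient") {
    year <- parts[2]
    ft <- reg$tables[[year]]
    if (is.null(ft)) return(api_error(404L, sprintf("no table for year %s", year)))

    parsed <- tryCatch(
      if (!is.null(body) && nzchar(body)) jsonlite::fromJSON(body, simplifyVector = FALSE)
      else list(),
      error = function(e) e)
    if (inherits(parsed, "error")) {
      return(api_error(400L, paste("malformed JSON body:", conditionMessage(parsed))))
    }

    if (method == "POST" && length(parts) == 3 && parts[3] == "cohort") {
      res <- tryCatch({
        cons <- parse_constraints(parsed$feature %||% list())
        cohort <- define_cohort(ft, cons)
        reg$cohorts[[year]][[cohort$cohort_id]] <- cohort
        list(status = 200L, content_type = "application/json",
             body = jsonlite::toJSON(list(cohort_id = cohort$cohort_id,
                                          size = cohort$size),
                                     auto_unbox = TRUE))
      }, opencohort_error = function(e) api_error(400L, conditionMessage(e)))
      return(res)
    }

    if (length(parts) >= 4 && parts[3] == "cohort") {
      cohort <- reg$cohorts[[year]][[parts[4]]]
      if (is.null(cohort)) return(api_error(404L, sprintf("unknown cohort %s", parts[4])))

      if (method == "GET" && length(parts) == 4) {
        return(list(status = 200L, content_type = "application/json",
                    body = jsonlite::toJSON(list(cohort_id = cohort$cohort_id,
                                                 constraints = cohort$constraints,
                                                 size = cohort$size),
                                            auto_unbox = TRUE)))
      }
      if (method == "POST" && length(parts) == 5 &&
          parts[5] == "associations_to_all_features") {
        res <- tryCatch({
          feats <- parsed$feature %||% list()
          if (length(feats) != 1) {
            abort("body must name exactly one outcome feature", "validation_error")
          }
          outc <- outcome_feature(names(feats)[1], feats[[1]]$operator, feats[[1]]$value)
          maxp <- parsed$maximum_p_value %||% 1
          battery <- associations_to_all_features(ft, cohort, outc,
                                                  maximum_p_value = maxp)
          if (grepl("text/tabular", accept, fixed = TRUE)) {
            list(status = 200L, content_type = "text/tabular",
                 body = format_tabular(battery))
          } else {
            list(status = 200L, content_type = "application/json",
                 body = jsonlite::toJSON(battery_payload(battery),
                                         auto_unbox = TRUE, digits = NA))
          }
        }, opencohort_error = function(e) api_error(400L, conditionMessage(e)))
        return(res)
      }
    }
  }
  api_error(404L, "no such route")
}

battery_payload <- function(x) {
  list(
    cohort_id = x$cohort_id,
    outcome = list(feature = x$outcome$name, operator = x$outcome$operator,
                   value = x$outcome$value),
    n_tested = x$m, alpha = x$alpha, alpha_adjusted = x$alpha_adjusted,
    correction = x$correction,
    results = lapply(unname(x$results), function(r) list(
      feature = r$feature,
      bins = r$table$col_labels,
      counts = lapply(seq_len(nrow(r$table$counts)),
                      function(i) unname(r$table$counts[i, ])),
      row_labels = r$table$row_labels,
      n_excluded_missing = r$table$n_excluded_missing,
      chi_square = r$chi_square, df = r$df, p_value = r$p_value,
      alpha_adjusted = r$alpha_adjusted, significant = r$significant)),
    skipped = as.list(x$skipped)
  )
}

api_description <- function(reg) {
  list(
    service = "opencohort association API",
    version = "0.1.0",
    years = names(reg$tables),
    paths = list(
      "GET /apispec" = "this description",
      "POST /patient/{year}/cohort" = "define a cohort from feature constraints",
      "GET /patient/{year}/cohort/{cohort_id}" = "cohort definition and size",
      "POST /patient/{year}/cohort/{cohort_id}/associations_to_all_features" =
        "chi-square battery of one outcome against all features"
    ),
    media_types = c("application/json", "text/tabular")
  )
}

#' Serve the association API over HTTP
#'
#' A minimal blocking HTTP/1.1 loop over a base-R server socket, intended
#' for local, single-user exploration (one request at a time, no TLS, no
#' authentication). Request handling is delegated to [handle_request()],
#' so CLI and HTTP paths produce identical output for identical inputs.
#'
#' @param reg a [table_registry()] with at least one table registered
#' @param port TCP port to bind on localhost
#' @param max_requests stop after this many requests (`Inf` to run until
#'   interrupted); useful for scripted runs
#' @return number of requests served, invisibly
#' @export
serve_api <- function(reg, port = 16340L, max_requests = Inf) {
  assert_that(length(reg$tables) >= 1, "register at least one table before serving",
              "configuration_error")
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  served <- 0
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 60)
    req <- tryCatch(read_http_request(con), error = function(e) NULL)
    if (!is.null(req)) {
      resp <- tryCatch(
        handle_request(reg, req$method, req$path, req$body, req$accept),
        error = function(e) api_error(500L, conditionMessage(e)))
      write_http_response(con, resp)
      served <- served + 1
    }
    close(con)
  }
  invisible(served)
}

read_http_request <- function(con) {
  request_line <- readLines(con, n = 1)
  if (!length(request_line)) stop("empty request")
  parts <- strsplit(request_line, " ", fixed = TRUE)[[1]]
  headers <- character()
  repeat {
    h <- readLines(con, n = 1)
    if (!length(h) || !nzchar(h)) break
    headers <- c(headers, h)
  }
  hget <- function(name) {
    hit <- grep(paste0("^", name, ":"), headers, ignore.case = TRUE, value = TRUE)
    if (length(hit)) trimws(sub("^[^:]+:", "", hit[1])) else ""
  }
  clen <- suppressWarnings(as.integer(hget("Content-Length")))
  body <- if (!is.na(clen) && clen > 0) rawToChar(readBin(con, "raw", clen)) else ""
  list(method = parts[1], path = parts[2], body = body,
       accept = hget("Accept"))
}

write_http_response <- function(con, resp) {
  body <- charToRaw(as.character(resp$body))
  status_text <- c(`200` = "OK", `400` = "Bad Request", `404` = "Not Found",
                   `500` = "Internal Server Error")[as.character(resp$status)]
  head <- sprintf(paste0("HTTP/1.1 %d %s\r\nContent-Type: %s\r\n",
                         "Content-Length: %d\r\nConnection: close\r\n\r\n"),
                  resp$status, status_text %||% "OK", resp$content_type, length(body))
  writeBin(c(charToRaw(head), body), con)
  flush(con)
}
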