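make_registry <- function(n = 500, seed = 18) {
  b <- generate_bundle(sim_config(seed = seed, n_patients = n))
  res <- run_pipeline(b, outcome = NULL)
  reg <- table_registry()
  all_id <- register_table(reg, res$table)
  list(reg = reg, all_id = all_id, table = res$table)
}

ed_query_body <- paste0('{"feature":{"TotalEDInpatientVisits":',
                        '{"operator":"=","value":0}},"maximum_p_value":1}')

table_registry_with <- function(ft) {
  reg <- table_registry()
  register_table(reg, ft)
  reg
}

test_that("the association endpoint answers the documented query shape", {
  x <- make_registry()
  path <- sprintf("/patient/2016/cohort/%s/associations_to_all_features", x$all_id)
  resp <- handle_request(x$reg, "POST", path, body = ed_query_body)
  expect_equal(resp$status, 200L)
  payload <- jsonlite::fromJSON(resp$body, simplifyVector = FALSE)
  # one result per eligible feature, none withheld at maximum_p_value = 1
  expect_equal(length(payload$results),
               payload$n_tested)
  expect_equal(payload$alpha_adjusted, 0.05 / payload$n_tested)
  feats <- vapply(payload$results, `[[`, "", "feature")
  expect_true(all(c("Sex", "AvgDailyPM25", "MedianIncome") %in% feats))

  # identical requests give byte-identical responses
  resp2 <- handle_request(x$reg, "POST", path, body = ed_query_body)
  expect_identical(resp2$body, resp$body)

  # text/tabular projection matches the battery's tabular rendering
  tab <- handle_request(x$reg, "POST", path, body = ed_query_body,
                        accept = "text/tabular")
  expect_equal(tab$content_type, "text/tabular")
  expect_match(tab$body, "^feature\t")

  # no identifier column name leaks into any response body
  for (body in list(resp$body, tab$body)) {
    for (ident in c("patient_id", "birth_date", "x_m", "y_m", "blockgroup_id")) {
      expect_false(grepl(ident, body, fixed = TRUE), label = ident)
    }
  }
})

test_that("cohort definition, lookup and error routes behave", {
  x <- make_registry(300, seed = 19)
  # define a sub-cohort over the API
  resp <- handle_request(x$reg, "POST", "/patient/2016/cohort",
                         body = '{"feature":{"Sex":{"operator":"=","value":"female"}}}')
  expect_equal(resp$status, 200L)
  def <- jsonlite::fromJSON(resp$body)
  expect_match(def$cohort_id, "^COHORT:")
  expect_equal(def$size, sum(x$table$rows$Sex == "female", na.rm = TRUE))
  # the new cohort is queryable
  got <- handle_request(x$reg, "GET",
                        sprintf("/patient/2016/cohort/%s", def$cohort_id))
  expect_equal(jsonlite::fromJSON(got$body)$size, def$size)

  expect_equal(handle_request(x$reg, "GET", "/patient/2016/cohort/COHORT:nope")$status,
               404L)
  expect_equal(handle_request(x$reg, "POST", "/patient/1999/cohort", body = "{}")$status,
               404L)
  expect_equal(handle_request(x$reg, "POST", "/patient/2016/cohort",
                              body = "{not json")$status, 400L)
  bad <- handle_request(x$reg, "POST",
                        sprintf("/patient/2016/cohort/%s/associations_to_all_features",
                                x$all_id),
                        body = '{"feature":{}}')
  expect_equal(bad$status, 400L)
  spec <- handle_request(x$reg, "GET", "/apispec")
  expect_equal(spec$status, 200L)
  expect_match(spec$body, "associations_to_all_features")
})

test_that("the HTTP loop serves a live request over loopback", {
  dir <- withr::local_tempdir()
  b <- generate_bundle(sim_config(seed = 23, n_patients = 200))
  res <- run_pipeline(b, outcome = NULL)
  tbl_path <- file.path(dir, "table.csv")
  write_feature_table(res$table, tbl_path)
  all_id <- define_cohort(res$table, list())$cohort_id

  port <- 20000 + (Sys.getpid() %% 20000)
  script <- file.path(dir, "server.R")
  writeLines(sprintf(
    'library(opencohort)
     reg <- table_registry()
     register_table(reg, read_feature_table("%s"))
     serve_api(reg, port = %d, max_requests = 1)',
    tbl_path, port), script)
  system2(file.path(R.home("bin"), "Rscript"), script, wait = FALSE,
          stdout = file.path(dir, "server.log"), stderr = file.path(dir, "server.log"))

  con <- NULL
  for (i in 1:60) {
    con <- tryCatch(socketConnection("127.0.0.1", port, blocking = TRUE,
                                     open = "r+b", timeout = 10),
                    error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(con)) break
    Sys.sleep(0.25)
  }
  expect_false(is.null(con))
  path <- sprintf("/patient/2016/cohort/%s/associations_to_all_features",
                  utils::URLencode(all_id, reserved = TRUE))
  req <- sprintf(paste0("POST %s HTTP/1.1\r\nHost: localhost\r\n",
                        "Accept: text/tabular\r\nContent-Type: application/json\r\n",
                        "Content-Length: %d\r\n\r\n%s"),
                 path, nchar(ed_query_body), ed_query_body)
  writeBin(charToRaw(req), con)
  flush(con)
  resp <- character()
  repeat {
    chunk <- tryCatch(suppressWarnings(readLines(con, n = 50)),
                      error = function(e) character())
    if (!length(chunk)) break
    resp <- c(resp, chunk)
  }
  close(con)
  expect_match(resp[1], "HTTP/1.1 200")
  body_start <- which(resp == "")[1] + 1
  expect_match(resp[body_start], "^feature\t")

  # HTTP and in-process paths agree on the payload
  direct <- handle_request(table_registry_with(res$table), "POST",
                           sprintf("/patient/2016/cohort/%s/associations_to_all_features",
                                   all_id),
                           body = ed_query_body, accept = "text/tabular")
  expect_equal(paste(resp[body_start:length(resp)], collapse = "\n"),
               sub("\n$", "", direct$body))
})

test_that("the CLI chains the pipeline end to end and is deterministic", {
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "b1"); out2 <- file.path(dir, "b2")
  expect_equal(cli_main(c("simulate", "--seed", "1", "--n", "400", "--out", out1)), 0L)
  expect_equal(cli_main(c("simulate", "--seed", "1", "--n", "400", "--out", out2)), 0L)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     label = f)
  }

  cohort_csv <- file.path(dir, "cohort.csv")
  expect_equal(cli_main(c("cohort", "--in", out1, "--out", cohort_csv)), 0L)
  expect_true(file.exists(cohort_csv))
  est_csv <- file.path(dir, "estimates.csv")
  expect_equal(cli_main(c("integrate", "--in", out1, "--out", est_csv)), 0L)
  tbl <- file.path(dir, "table.csv")
  expect_equal(cli_main(c("bin", "--in", out1, "--out", tbl)), 0L)
  expect_true(file.exists(paste0(tbl, ".meta.json")))

  out <- capture.output(code <- cli_main(c("table", "summarize", "--table", tbl,
                                           "--feature", "Sex")))
  expect_equal(code, 0L)
  expect_true(any(grepl("female", out)))

  out <- capture.output(code <- cli_main(c("associate", "--table", tbl)))
  expect_equal(code, 0L)
  expect_match(out[1], "^feature\t")
  # a maximum p-value of zero yields an empty (header-only) result, exit 0
  out0 <- capture.output(code0 <- cli_main(c("associate", "--table", tbl,
                                             "--max-p", "0")))
  expect_equal(code0, 0L)
  expect_equal(length(out0), 1L)

  # the open artifacts never contain identifier columns
  for (f in c(tbl)) {
    expect_true(assert_no_identifiers(names(data.table::fread(f, nrows = 0))))
  }

  # usage errors exit 2
  expect_equal(cli_main(character()), 2L)
  expect_equal(cli_main(c("frobnicate")), 2L)
  expect_equal(suppressWarnings(cli_main(c("simulate", "--seed"))), 2L)
  # runtime validation errors exit 1
  expect_equal(cli_main(c("cohort", "--in", file.path(dir, "missing"))), 1L)
})
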