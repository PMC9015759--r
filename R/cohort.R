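#' Cohort inclusion criteria
#'
#' Configurable code sets and thresholds for the four inclusion rules of
#' the asthma-and-related-conditions cohort:
#'
#' 1. an asthma diagnosis code AND a prescribed/administered asthma
#'    medication;
#' 2. a non-asthma respiratory diagnosis AND an asthma medication;
#' 3. a non-asthma pulmonary diagnosis AND an asthma-management test or
#'    procedure;
#' 4. a non-asthma respiratory diagnosis AND at least
#'    `frequent_ed_threshold` emergency-department encounters in the
#'    study year in which a nebulizer medication was administered.
#'
#' Published cohorts of this kind cite licensed terminology value sets;
#' here the code sets are plain configuration with a shipped synthetic
#' vocabulary, so the logic is reproducible without licensed
#' terminologies.
#'
#' @param asthma_dx_codes,respiratory_dx_codes,pulmonary_dx_codes
#'   diagnosis code sets (respiratory/pulmonary sets are the non-asthma
#'   sets used by rules 2-4)
#' @param asthma_med_codes,nebulizer_med_codes medication code sets
#' @param asthma_proc_codes test/procedure code set (rule 3; laboratory
#'   measures fold in here)
#' @param frequent_ed_threshold minimum qualifying ED visits for rule 4
#' @return object of class `cohort_criteria`
#' @export
cohort_criteria <- function(asthma_dx_codes,
                            respiratory_dx_codes,
                            pulmonary_dx_codes,
                            asthma_med_codes,
                            asthma_proc_codes,
                            nebulizer_med_codes,
                            frequent_ed_threshold = 2L) {
  sets <- list(asthma_dx_codes = asthma_dx_codes,
               respiratory_dx_codes = respiratory_dx_codes,
               pulmonary_dx_codes = pulmonary_dx_codes,
               asthma_med_codes = asthma_med_codes,
               asthma_proc_codes = asthma_proc_codes,
               nebulizer_med_codes = nebulizer_med_codes)
  empty <- names(sets)[!vapply(sets, length, 0L)]
  if (length(empty)) {
    abort(sprintf("empty code set(s): %s", paste(empty, collapse = ", ")),
          "configuration_error")
  }
  assert_that(frequent_ed_threshold >= 1, "frequent_ed_threshold must be >= 1",
              "configuration_error")
  structure(c(sets, list(frequent_ed_threshold = as.integer(frequent_ed_threshold))),
            class = "cohort_criteria")
}

#' Default cohort criteria (synthetic vocabulary)
#'
#' @param path optional YAML criteria file; defaults to the shipped
#'   `inst/extdata/default_criteria.yaml`
#' @return a [cohort_criteria]
#' @export
default_criteria <- function(path = NULL) {
  path <- path %||% system.file("extdata", "default_criteria.yaml",
                                package = "opencohort", mustWork = TRUE)
  read_criteria(path)
}

#' Read / write cohort criteria as YAML
#'
#' @param path YAML file path
#' @return `read_criteria`: a [cohort_criteria]; `write_criteria`: `path`
#'   invisibly
#' @export
read_criteria <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort_criteria(
    asthma_dx_codes = as.character(raw$asthma_dx_codes),
    respiratory_dx_codes = as.character(raw$respiratory_dx_codes),
    pulmonary_dx_codes = as.character(raw$pulmonary_dx_codes),
    asthma_med_codes = as.character(raw$asthma_med_codes),
    asthma_proc_codes = as.character(raw$asthma_proc_codes),
    nebulizer_med_codes = as.character(raw$nebulizer_med_codes),
    frequent_ed_threshold = as.integer(raw$frequent_ed_threshold %||% 2L)
  )
}

#' @rdname read_criteria
#' @param criteria a [cohort_criteria]
#' @export
write_criteria <- function(criteria, path) {
  yaml::write_yaml(lapply(unclass(criteria), function(x)
    if (length(x) > 1) as.list(x) else x), path)
  invisible(path)
}

validate_encounters <- function(encounters) {
  ok_class <- c("ED", "inpatient", "outpatient")
  bad <- setdiff(unique(encounters$encounter_class), ok_class)
  if (length(bad)) {
    abort(sprintf("unknown encounter_class: %s", paste(bad, collapse = ", ")),
          "validation_error")
  }
  bad_type <- setdiff(unique(encounters$code_type), c("dx", "med", "proc"))
  if (length(bad_type)) {
    abort(sprintf("unknown code_type: %s", paste(bad_type, collapse = ", ")),
          "validation_error")
  }
  invisible(TRUE)
}

#' Select the analysis cohort
#'
#' Applies the four inclusion rules (see [cohort_criteria()]) and returns
#' their union, with each rule's member set also reported separately.
#' Rules 1-3 consider coded events from any encounter; rule 4 counts
#' distinct ED encounter dates within the study year on which a nebulizer
#' medication was administered.
#'
#' @param patients data.frame with `patient_id`
#' @param encounters data.frame with `patient_id, date, encounter_class,
#'   code_type, code` (one coded event per row)
#' @param criteria a [cohort_criteria]
#' @param study_year integer calendar year (rule 4's ED-visit window)
#' @return list with `cohort` (character vector of patient ids, sorted)
#'   and `rules` (list of four id vectors, possibly overlapping)
#' @export
select_cohort <- function(patients, encounters, criteria, study_year) {
  assert_that(inherits(criteria, "cohort_criteria"), "criteria must be cohort_criteria",
              "configuration_error")
  if (!nrow(encounters) || !nrow(patients)) {
    return(list(cohort = character(),
                rules = list(rule1 = character(), rule2 = character(),
                             rule3 = character(), rule4 = character())))
  }
  validate_encounters(encounters)
  e <- data.table::as.data.table(encounters)
  e[, patient_id := as.character(patient_id)]
  e[, date := as.Date(date)]

  ids_with <- function(type, codes, sub = e) {
    unique(sub[code_type == type & code %in% codes, patient_id])
  }
  has_asthma_dx <- ids_with("dx", criteria$asthma_dx_codes)
  has_resp_dx   <- ids_with("dx", criteria$respiratory_dx_codes)
  has_pulm_dx   <- ids_with("dx", criteria$pulmonary_dx_codes)
  has_asthma_med <- ids_with("med", criteria$asthma_med_codes)
  has_asthma_proc <- ids_with("proc", criteria$asthma_proc_codes)

  ed_year <- e[encounter_class == "ED" &
                 as.integer(format(date, "%Y")) == study_year &
                 code_type == "med" & code %in% criteria$nebulizer_med_codes]
  ed_counts <- ed_year[, .(n_visits = data.table::uniqueN(date)), by = patient_id]
  frequent_ed <- ed_counts[n_visits >= criteria$frequent_ed_threshold, patient_id]

  rule1 <- intersect(has_asthma_dx, has_asthma_med)
  rule2 <- intersect(has_resp_dx, has_asthma_med)
  rule3 <- intersect(has_pulm_dx, has_asthma_proc)
  rule4 <- intersect(has_resp_dx, frequent_ed)

  roster <- as.character(patients$patient_id)
  rules <- lapply(list(rule1 = rule1, rule2 = rule2, rule3 = rule3, rule4 = rule4),
                  function(r) sort(intersect(r, roster)))
  list(cohort = sort(unique(unlist(rules, use.names = FALSE))), rules = rules)
}

#' Count annual outcome events per patient
#'
#' Outcome tallies for the study year: `TotalEDInpatientVisits` counts
#' distinct ED/inpatient encounter dates carrying a respiratory or asthma
#' diagnosis; `TotalPrednisoneRx` counts prednisone
#' prescription/administration events.
#'
#' @param encounters encounter data.frame (see [select_cohort()])
#' @param patient_ids patients to report (zero-filled if no events)
#' @param criteria a [cohort_criteria] (supplies the respiratory dx sets)
#' @param study_year integer calendar year
#' @param prednisone_codes medication codes counted as prednisone
#' @return data.frame `patient_id, TotalEDInpatientVisits,
#'   TotalPrednisoneRx`
#' @export
count_outcomes <- function(encounters, patient_ids, criteria, study_year,
                           prednisone_codes = "PREDNISONE") {
  patient_ids <- as.character(patient_ids)
  out <- data.table::data.table(patient_id = patient_ids)
  if (nrow(encounters)) {
    e <- data.table::as.data.table(encounters)
    e[, patient_id := as.character(patient_id)]
    e[, date := as.Date(date)]
    e <- e[as.integer(format(date, "%Y")) == study_year]
    resp_codes <- c(criteria$asthma_dx_codes, criteria$respiratory_dx_codes)
    ed <- e[encounter_class %in% c("ED", "inpatient") & code_type == "dx" &
              code %in% resp_codes,
            .(TotalEDInpatientVisits = data.table::uniqueN(date)), by = patient_id]
    rx <- e[code_type == "med" & code %in% prednisone_codes,
            .(TotalPrednisoneRx = .N), by = patient_id]
    out <- merge(out, ed, by = "patient_id", all.x = TRUE)
    out <- merge(out, rx, by = "patient_id", all.x = TRUE)
  } else {
    out[, `:=`(TotalEDInpatientVisits = NA_integer_, TotalPrednisoneRx = NA_integer_)]
  }
  out[is.na(TotalEDInpatientVisits), TotalEDInpatientVisits := 0L]
  out[is.na(TotalPrednisoneRx), TotalPrednisoneRx := 0L]
  data.frame(out[match(patient_ids, patient_id)], stringsAsFactors = FALSE)
}
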