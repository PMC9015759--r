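#' Assemble the raw per-patient analysis frame
#'
#' Joins the cohort roster, exposure estimates and annual outcome tallies
#' into one raw row per cohort patient — the frame that [deidentify()]
#' turns into an open feature table. Columns are the feature names the
#' default schemes expect (`Sex`, `Race`, `Ethnicity`,
#' `ResidentialDensity`, `ProbNoInsurance`, `MedianIncome`,
#' `RoadwayDistance`, `AvgDailyPM25`, `MaxDailyOzone`), the raw
#' `birth_date` (binned to age downstream), any `cov_*` covariate
#' columns, and the outcome counts.
#'
#' @param patients patient extract data.frame
#' @param estimates output of [integrate_exposures()]
#' @param outcomes output of [count_outcomes()]
#' @param cohort_ids patient ids to keep (the selected cohort)
#' @return data.frame, one row per cohort patient
#' @export
build_patient_frame <- function(patients, estimates, outcomes, cohort_ids) {
  p <- patients[match(cohort_ids, patients$patient_id), , drop = FALSE]
  e <- estimates[match(cohort_ids, estimates$patient_id), , drop = FALSE]
  o <- outcomes[match(cohort_ids, outcomes$patient_id), , drop = FALSE]
  out <- data.frame(
    patient_id = p$patient_id, birth_date = p$birth_date,
    Sex = p$sex, Race = p$race, Ethnicity = p$ethnicity,
    ResidentialDensity = e$density_class,
    ProbNoInsurance = e$prob_no_insurance,
    MedianIncome = e$median_income,
    RoadwayDistance = e$roadway_distance,
    AvgDailyPM25 = e$avg_daily_pm25,
    MaxDailyOzone = e$avg_max_daily_ozone,
    TotalEDInpatientVisits = o$TotalEDInpatientVisits,
    TotalPrednisoneRx = o$TotalPrednisoneRx,
    stringsAsFactors = FALSE
  )
  covs <- grep("^cov_", names(p), value = TRUE)
  for (cv in covs) out[[cv]] <- p[[cv]]
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on a bundle
#'
#' The end-to-end chain: select the cohort from the raw records,
#' integrate environmental and socioeconomic exposures for the selected
#' patients, bin and de-identify into a feature table, and (optionally)
#' run the chi-square association battery against an outcome.
#'
#' @param bundle a `synthetic_bundle` (from [generate_bundle()] or
#'   [read_bundle()])
#' @param criteria a [cohort_criteria]; default shipped criteria
#' @param schemes named list of binning schemes; default shipped schemes
#' @param study_year study year; defaults to the bundle's
#' @param outcome an [outcome_feature] or `NULL` to stop after building
#'   the table
#' @param maximum_p_value,alpha,correction passed to
#'   [associations_to_all_features()]
#' @return list with `cohort` (selection result), `table` (the
#'   [feature_table]) and `battery` (an `association_battery`, or `NULL`)
#' @export
run_pipeline <- function(bundle,
                         criteria = default_criteria(),
                         schemes = default_schemes(),
                         study_year = NULL,
                         outcome = outcome_feature("TotalEDInpatientVisits", "=", 0),
                         maximum_p_value = 1, alpha = 0.05,
                         correction = "bonferroni") {
  study_year <- study_year %||% bundle$config$study_year
  sel <- select_cohort(bundle$patients, bundle$encounters, criteria, study_year)
  roster <- bundle$patients[bundle$patients$patient_id %in% sel$cohort, , drop = FALSE]
  est <- integrate_exposures(roster, pm25 = bundle$pm25, ozone = bundle$ozone,
                             roadways = bundle$roadways,
                             blockgroups = bundle$blockgroups,
                             study_year = study_year)
  out <- count_outcomes(bundle$encounters, sel$cohort, criteria, study_year)
  raw <- build_patient_frame(roster, est, out, sel$cohort)

  covs <- grep("^cov_", names(raw), value = TRUE)
  for (cv in covs) {
    schemes[[cv]] <- binning_scheme(cv, "categorical_passthrough",
                                    levels = c("A", "B", "C"))
  }
  ft <- deidentify(raw, schemes, identifiers = default_identifiers(),
                   study_year = study_year,
                   count_features = c("TotalEDInpatientVisits", "TotalPrednisoneRx"))
  battery <- NULL
  if (!is.null(outcome)) {
    cohort <- define_cohort(ft, list())
    battery <- associations_to_all_features(ft, cohort, outcome,
                                            maximum_p_value = maximum_p_value,
                                            alpha = alpha, correction = correction)
  }
  list(cohort = sel, table = ft, battery = battery)
}
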