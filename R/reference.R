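#' Reference association tables from a published asthma cohort
#'
#' Ten 2 x k contingency tables reconstructed from the printed group
#' counts of a large published asthma cohort analysis (N = 157,410;
#' 26,332 patients with >= 1 annual ED/inpatient visit for respiratory
#' issues, 17,056 with >= 1 annual prednisone prescription). Each entry
#' carries the per-bin event counts and totals, the reconstructed
#' 2-row count matrix (row 1 = no event, row 2 = >= 1 event), and the
#' chi-square statistic the source reported, for validating the
#' chi-square engine against published values.
#'
#' @return named list; each element has `feature`, `outcome`,
#'   `col_labels`, `events`, `totals`, `table` (a `contingency_table`)
#'   and `published_chi_square`
#' @export
reference_association_tables <- function() {
  mk <- function(feature, outcome, labels, events, totals, published) {
    counts <- rbind(totals - events, events)
    list(feature = feature, outcome = outcome, col_labels = labels,
         events = events, totals = totals,
         table = contingency_table(counts,
                                   row_labels = c("0 events", ">=1 events"),
                                   col_labels = labels, feature = feature),
         published_chi_square = published)
  }
  list(
    sex_ed = mk("Sex", "ed_visits", c("Female", "Male"),
                c(15587, 10743), c(89531, 67875), 69.4),
    race_ed = mk("Race", "ed_visits", c("Caucasian", "African American"),
                 c(9304, 3137), c(78418, 28977), 22.3),
    age_ed = mk("AgeStudyStart", "ed_visits",
                c("<5", "5-17", "18-44", "45-64", "65-89"),
                c(914, 2576, 4655, 8822, 9365),
                c(5638, 20071, 35777, 51495, 44429), 1245.5),
    density_ed = mk("ResidentialDensity", "ed_visits",
                    c("rural", "urban cluster"),
                    c(18739, 7155), c(95632, 41798), 116.7),
    insurance_ed = mk("ProbNoInsurance", "ed_visits",
                      c("[0, 0.0637]", "(0.0637, 0.1121]",
                        "(0.1121, 0.1644]", "(0.1644, 0.5548]"),
                      c(5681, 6325, 6878, 7000),
                      c(34500, 34313, 34340, 34201), 221.7),
    income_ed = mk("MedianIncome", "ed_visits",
                   c("[7470, 36635]", "(36635, 46750]", "(46750, 59566]",
                     "(59566, 78355]", "(78355, 250001]"),
                   c(5847, 5553, 5127, 4872, 3898),
                   c(26967, 27081, 26843, 26968, 26955), 542.5),
    roadway_ed = mk("RoadwayDistance", "ed_visits",
                    c("0-49", "50-99", "100-149", "150-199", "200-249", ">=250"),
                    c(3516, 1800, 2021, 1850, 1607, 15529),
                    c(17485, 9754, 10244, 9398, 8477, 85989), 59.6),
    pm25_ed = mk("AvgDailyPM25", "ed_visits",
                 c("[3.27, 6.30]", "(6.30, 7.81]", "(7.81, 10.83]"),
                 c(300, 1017, 24975), c(2170, 6636, 132206), 86.7),
    ozone_ed = mk("MaxDailyOzone", "ed_visits",
                  c("[27.80, 39.00]", "(39.00, 42.73]", "(42.73, 46.45]"),
                  c(21, 1749, 24522), c(236, 11372, 129404), 102.6),
    age_prednisone = mk("AgeStudyStart", "prednisone",
                        c("<5", "5-17", "18-44", "45-64", "65-89"),
                        c(15, 1235, 3861, 6222, 5723),
                        c(5638, 20071, 35777, 51495, 44429), 1382.8)
  )
}

#' Reference cohort marginals
#'
#' Marginal distributions (per-bin proportions, missing fractions, and
#' outcome prevalences) of the same published cohort; these are the
#' default marginal specification of the synthetic generator.
#'
#' @return a nested list of proportions
#' @export
reference_marginals <- function() {
  list(
    n = 157410,
    prevalence_ed = 0.1673,
    prevalence_prednisone = 0.1084,
    age = c("<5" = 0.0358, "5-17" = 0.1275, "18-44" = 0.2273,
            "45-64" = 0.3271, "65-89" = 0.2823),
    sex = c(male = 0.4312, female = 0.5688),
    race = c("Caucasian" = 0.4982, "African American" = 0.1841,
             "Asian" = 0.0102, "American/Alaskan Native" = 0.0057,
             "Native Hawaiian/Pacific Islander" = 0.0004,
             "Unknown/other" = 0.3014),
    ethnicity = c("Hispanic" = 0.0476, "Not Hispanic" = 0.6729,
                  "Unknown" = 0.2795),
    # conditional on non-missing
    density = c("rural" = 0.6959, "urban cluster" = 0.3041),
    insurance = c(0.25, 0.25, 0.25, 0.25),
    income = c(0.2, 0.2, 0.2, 0.2, 0.2),
    roadway = c(0.1579, 0.0881, 0.0925, 0.0849, 0.0766, 0.7766) /
      sum(c(0.1579, 0.0881, 0.0925, 0.0849, 0.0766, 0.7766)),
    pm25 = c(0.0625, 0.7719, 0.1657) / sum(c(0.0625, 0.7719, 0.1657)),
    ozone = c(0.0823, 0.9021, 0.0156) / sum(c(0.0823, 0.9021, 0.0156)),
    # total missing fractions (geocode-driven base is pm25/ozone's 0.1042)
    missing = c(geocode = 0.1042, density = 0.1269, insurance = 0.1274,
                income = 0.1435),
    # per-bin event rates for >=1 annual ED/inpatient respiratory visit,
    # used to derive the default planted log-odds offsets
    ed_bin_rates = list(
      AgeStudyStart = c(0.1621, 0.1283, 0.1301, 0.1713, 0.2108),
      Sex = c(male = 0.1583, female = 0.1741),
      ResidentialDensity = c("rural" = 0.1959, "urban cluster" = 0.1712),
      ProbNoInsurance = c(0.1647, 0.1843, 0.2003, 0.2047),
      MedianIncome = c(0.2168, 0.2051, 0.1910, 0.1807, 0.1446),
      RoadwayDistance = c(0.2011, 0.1845, 0.1973, 0.1969, 0.1896, 0.1806),
      AvgDailyPM25 = c(0.1382, 0.1533, 0.1889),
      MaxDailyOzone = c(0.0890, 0.1538, 0.1895)
    ),
    prednisone_bin_rates = list(
      AgeStudyStart = c(0.0027, 0.0610, 0.1079, 0.1208, 0.1288)
    )
  )
}
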