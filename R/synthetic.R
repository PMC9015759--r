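#' Synthetic EHR simulation configuration
#'
#' Defines the study conditions for the seeded synthetic population. The
#' defaults emulate the published reference cohort (see
#' [reference_marginals()]): N = 157,410 patients in study year 2016,
#' outcome prevalences 16.73% (>= 1 annual ED/inpatient visit for
#' respiratory issues) and 10.84% (>= 1 annual prednisone prescription),
#' marginal distributions of age / sex / race / exposures matching the
#' published table, and planted per-bin log-odds offsets derived from the
#' published per-bin event rates (monotone effects for income, insurance,
#' PM2.5, ozone and roadway proximity; a U-shaped age effect on ED
#' visits and a monotone one on prednisone).
#'
#' Geography is a synthetic planar 100 km x 100 km region in meters:
#' PM2.5 varies along x (3 bin strips x 10 subcells), ozone along y,
#' major roadways are vertical highways every 1000 m, and census block
#' groups are a rectangular tiling carrying density / insurance / income
#' attributes. Patients are assigned binned feature values first (the
#' outcome model runs on the bins), then coordinates and context data are
#' constructed so that exposure integration plus the default binning
#' schemes recover exactly the assigned bins.
#'
#' @param seed integer RNG seed; identical configs give byte-identical
#'   written bundles
#' @param n_patients number of cohort patients to simulate
#' @param study_year calendar year
#' @param prevalence_ed,prevalence_prednisone target outcome prevalences
#' @param marginals per-feature bin proportions (each summing to 1); see
#'   [reference_marginals()] for the default structure
#' @param effects_ed,effects_prednisone named lists of per-bin log-odds
#'   offsets (one numeric vector per feature, matching that feature's bin
#'   count); offsets are centered under the feature's marginal before use
#' @param missing_rates total missing fractions: `geocode` (drives PM2.5,
#'   ozone and roadway missingness), `density`, `insurance`, `income`
#' @param frac_noncohort fraction of additional patients that do not meet
#'   any inclusion rule (exercise the cohort selector)
#' @param n_null_covariates extra 3-level categorical covariates with no
#'   planted effect, appended as `cov_01`, `cov_02`, ...
#' @param frequent_ed_threshold rule-4 ED visit threshold the generator
#'   guarantees for its rule-4 patients
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 157410L,
                       study_year = 2016L,
                       prevalence_ed = 0.1673,
                       prevalence_prednisone = 0.1084,
                       marginals = NULL,
                       effects_ed = NULL,
                       effects_prednisone = NULL,
                       missing_rates = NULL,
                       frac_noncohort = 0.05,
                       n_null_covariates = 0L,
                       frequent_ed_threshold = 2L) {
  ref <- reference_marginals()
  marginals <- utils::modifyList(list(
    age = ref$age, sex = ref$sex, race = ref$race, ethnicity = ref$ethnicity,
    density = ref$density, insurance = ref$insurance, income = ref$income,
    roadway = ref$roadway, pm25 = ref$pm25, ozone = ref$ozone
  ), marginals %||% list())
  missing_rates <- utils::modifyList(as.list(ref$missing), missing_rates %||% list())

  if (is.null(effects_ed)) effects_ed <- default_effects(ref$ed_bin_rates, marginals)
  if (is.null(effects_prednisone)) {
    rates <- ref$ed_bin_rates
    rates$AgeStudyStart <- ref$prednisone_bin_rates$AgeStudyStart
    effects_prednisone <- default_effects(rates, marginals)
  }

  cfg <- structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    study_year = as.integer(study_year),
    prevalence_ed = prevalence_ed, prevalence_prednisone = prevalence_prednisone,
    marginals = marginals, effects_ed = effects_ed,
    effects_prednisone = effects_prednisone,
    missing_rates = missing_rates, frac_noncohort = frac_noncohort,
    n_null_covariates = as.integer(n_null_covariates),
    frequent_ed_threshold = as.integer(frequent_ed_threshold)
  ), class = "sim_config")
  validate_config(cfg)
  cfg
}

# feature name -> marginal key used when centering effect offsets
feature_marginal_key <- c(
  AgeStudyStart = "age", Sex = "sex", Race = "race", Ethnicity = "ethnicity",
  ResidentialDensity = "density", ProbNoInsurance = "insurance",
  MedianIncome = "income", RoadwayDistance = "roadway",
  AvgDailyPM25 = "pm25", MaxDailyOzone = "ozone"
)

# Published per-bin event rates -> centered log-odds offsets.
default_effects <- function(bin_rates, marginals) {
  out <- list()
  for (f in names(bin_rates)) {
    lo <- stats::qlogis(as.numeric(bin_rates[[f]]))
    w <- as.numeric(marginals[[feature_marginal_key[[f]]]])
    if (length(w) != length(lo)) {
      abort(sprintf("marginal spec for '%s' must have %d bins", f, length(lo)),
            "configuration_error")
    }
    out[[f]] <- lo - sum(lo * w) / sum(w)
  }
  out
}

validate_config <- function(cfg) {
  assert_that(is_probability(cfg$prevalence_ed) &&
                is_probability(cfg$prevalence_prednisone),
              "outcome prevalences must be probabilities", "configuration_error")
  for (nm in names(cfg$marginals)) {
    p <- as.numeric(cfg$marginals[[nm]])
    assert_that(length(p) > 0, sprintf("empty bin spec for '%s'", nm),
                "configuration_error")
    assert_that(all(p >= 0 & p <= 1), sprintf("'%s' proportions outside [0,1]", nm),
                "configuration_error")
    assert_that(abs(sum(p) - 1) < 1e-6, sprintf("'%s' proportions must sum to 1", nm),
                "configuration_error")
  }
  for (nm in names(cfg$missing_rates)) {
    assert_that(is_probability(cfg$missing_rates[[nm]]),
                sprintf("missing rate '%s' outside [0,1]", nm), "configuration_error")
  }
  for (eff in list(cfg$effects_ed, cfg$effects_prednisone)) {
    for (f in names(eff)) {
      k <- length(cfg$marginals[[feature_marginal_key[[f]]]])
      assert_that(length(eff[[f]]) == k,
                  sprintf("effect offsets for '%s' must have %d entries", f, k),
                  "configuration_error")
    }
  }
  assert_that(is_probability(cfg$frac_noncohort), "frac_noncohort outside [0,1]",
              "configuration_error")
  invisible(TRUE)
}

region_size <- 100000  # meters
road_spacing <- 1000   # meters between vertical highways

pm25_bin_edges  <- c(3.27, 6.30, 7.81, 10.83)
ozone_bin_edges <- c(27.80, 39.00, 42.73, 46.45)
roadway_bin_lo  <- c(0, 50, 100, 150, 200, 250)
roadway_bin_hi  <- c(50, 100, 150, 200, 250, 500)
insurance_edges <- c(0, 0.0637, 0.1121, 0.1644, 0.5548)
income_edges    <- c(7470, 36635, 46750, 59566, 78355, 250001)

age_bin_lo <- c(0, 5, 18, 45, 65)
age_bin_hi <- c(4, 17, 44, 64, 89)

# per-bin target annual means strictly inside each bin interval
strip_targets <- function(edges, n_sub) {
  unlist(lapply(seq_len(length(edges) - 1L), function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    seq(lo + 0.06 * (hi - lo), hi - 0.06 * (hi - lo), length.out = n_sub)
  }))
}

make_surface_geometry <- function(pollutant, n_sub = 10L) {
  edges <- if (pollutant == "pm25") pm25_bin_edges else ozone_bin_edges
  n_bins <- length(edges) - 1L
  n_cells <- n_bins * n_sub
  width <- region_size / n_cells
  lo <- (seq_len(n_cells) - 1L) * width
  hi <- lo + width
  cells <- if (pollutant == "pm25") {
    data.frame(cell_id = sprintf("PM%03d", seq_len(n_cells)),
               xmin = lo, xmax = hi, ymin = 0, ymax = region_size,
               stringsAsFactors = FALSE)
  } else {
    data.frame(cell_id = sprintf("OZ%03d", seq_len(n_cells)),
               xmin = 0, xmax = region_size, ymin = lo, ymax = hi,
               stringsAsFactors = FALSE)
  }
  cells$bin <- rep(seq_len(n_bins), each = n_sub)
  cells$target <- strip_targets(edges, n_sub)
  cells
}

# Daily series per cell: seasonal sinusoid + Gaussian noise, shifted so the
# annual mean equals the cell's target exactly.
make_surface_values <- function(cells, study_year, amplitude, sd) {
  days <- seq(as.Date(sprintf("%d-01-01", study_year)),
              as.Date(sprintf("%d-12-31", study_year)), by = "day")
  t <- as.numeric(days - days[1])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    phase <- stats::runif(1, 0, 2 * pi)
    v <- cells$target[i] + amplitude * sin(2 * pi * t / 365.25 + phase) +
      stats::rnorm(length(t), 0, sd)
    v <- v + (cells$target[i] - mean(v))
    out[[i]] <- data.frame(cell_id = cells$cell_id[i], date = days, value = v,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

make_roadways <- function() {
  xs <- seq(0, region_size, by = road_spacing)
  data.frame(segment_id = sprintf("RD%03d", seq_along(xs)),
             x1 = xs, y1 = 0, x2 = xs, y2 = region_size,
             road_class = "highway", stringsAsFactors = FALSE)
}

# One block-group tile per (density x insurance x income) attribute combo,
# missing-attribute variants included; tiles form a rectangular tiling.
make_blockgroups <- function() {
  dens <- c("rural", "urban cluster", NA)
  ins_bin <- c(1:4, NA)
  inc_bin <- c(1:5, NA)
  combos <- expand.grid(density = dens, insurance = ins_bin, income = inc_bin,
                        stringsAsFactors = FALSE)
  n <- nrow(combos)  # 90
  ncol_t <- 10L; nrow_t <- ceiling(n / ncol_t)
  w <- region_size / ncol_t; h <- region_size / nrow_t
  i <- seq_len(n) - 1L
  mid <- function(edges, b) (edges[b] + edges[b + 1]) / 2
  data.frame(
    blockgroup_id = sprintf("BG%03d", seq_len(n)),
    population = ifelse(is.na(combos$density), NA,
                        ifelse(combos$density == "rural", 1200, 26000)),
    prob_no_insurance = ifelse(is.na(combos$insurance), NA,
                               mid(insurance_edges, combos$insurance)),
    median_income = ifelse(is.na(combos$income), NA,
                           mid(income_edges, combos$income)),
    xmin = (i %% ncol_t) * w, xmax = (i %% ncol_t + 1) * w,
    ymin = (i %/% ncol_t) * h, ymax = (i %/% ncol_t + 1) * h,
    density = combos$density, insurance_bin = combos$insurance,
    income_bin = combos$income, stringsAsFactors = FALSE
  )
}

draw_bins <- function(n, props) {
  sample.int(length(props), n, replace = TRUE, prob = as.numeric(props))
}

# deterministic distinct days within the year for per-patient visit dates
distinct_days <- function(base, j, n_days) ((base + j * 17L) %% n_days) + 1L

#' Generate a synthetic patient bundle
#'
#' Draws a seeded synthetic population per the configuration (see
#' [sim_config()]): binned feature values from the marginal specs,
#' outcome indicators from a logistic model whose intercept is calibrated
#' so the expected prevalence equals the configured one under the planted
#' per-bin log-odds offsets, then raw records — patients with geocodes,
#' dated coded encounters (inclusion-rule qualifying events, outcome
#' events, prednisone prescriptions), daily pollutant surfaces, roadway
#' segments, and census block groups — constructed so that the downstream
#' pipeline recovers the assigned bins exactly.
#'
#' @param config a [sim_config()]
#' @return object of class `synthetic_bundle`: `patients`, `encounters`,
#'   `pm25`, `ozone` ([exposure_surface]s), `roadways`, `blockgroups`,
#'   `truth` (the planted effects and per-patient assigned bins),
#'   `config`
#' @export
generate_bundle <- function(config) {
  validate_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  yr <- config$study_year
  n <- config$n_patients
  n_extra <- as.integer(round(config$frac_noncohort * n))
  mg <- config$marginals

  pm_cells <- make_surface_geometry("pm25")
  oz_cells <- make_surface_geometry("ozone")
  pm_values <- make_surface_values(pm_cells, yr, amplitude = 1.0, sd = 0.4)
  oz_values <- make_surface_values(oz_cells, yr, amplitude = 4.0, sd = 1.5)
  roadways <- make_roadways()
  bg <- make_blockgroups()

  if (n == 0L && n_extra == 0L) {
    return(empty_bundle(config, pm_cells, oz_cells, pm_values, oz_values,
                        roadways, bg))
  }

  n_all <- n + n_extra
  is_cohort <- c(rep(TRUE, n), rep(FALSE, n_extra))

  # --- binned feature assignment -------------------------------------------
  age_bin <- draw_bins(n_all, mg$age)
  sex_bin <- draw_bins(n_all, mg$sex)
  race_bin <- draw_bins(n_all, mg$race)
  eth_bin <- draw_bins(n_all, mg$ethnicity)
  geo_missing <- stats::runif(n_all) < config$missing_rates$geocode
  cond_rate <- function(total) {
    max(0, (total - config$missing_rates$geocode) / (1 - config$missing_rates$geocode))
  }
  dens_bin <- draw_bins(n_all, mg$density)
  dens_bin[stats::runif(n_all) < cond_rate(config$missing_rates$density)] <- NA
  ins_bin <- draw_bins(n_all, mg$insurance)
  ins_bin[stats::runif(n_all) < cond_rate(config$missing_rates$insurance)] <- NA
  inc_bin <- draw_bins(n_all, mg$income)
  inc_bin[stats::runif(n_all) < cond_rate(config$missing_rates$income)] <- NA
  road_bin <- draw_bins(n_all, mg$roadway)
  pm_bin <- draw_bins(n_all, mg$pm25)
  oz_bin <- draw_bins(n_all, mg$ozone)
  # geocode-derived and census features all missing when geocode is missing
  dens_bin[geo_missing] <- NA; ins_bin[geo_missing] <- NA; inc_bin[geo_missing] <- NA
  road_bin[geo_missing] <- NA; pm_bin[geo_missing] <- NA; oz_bin[geo_missing] <- NA

  covs <- NULL
  if (config$n_null_covariates > 0) {
    covs <- as.data.frame(stats::setNames(
      lapply(seq_len(config$n_null_covariates), function(i)
        c("A", "B", "C")[draw_bins(n_all, c(1, 1, 1) / 3)]),
      sprintf("cov_%02d", seq_len(config$n_null_covariates))),
      stringsAsFactors = FALSE)
  }

  bins <- list(AgeStudyStart = age_bin, Sex = sex_bin, Race = race_bin,
               Ethnicity = eth_bin, ResidentialDensity = dens_bin,
               ProbNoInsurance = ins_bin, MedianIncome = inc_bin,
               RoadwayDistance = road_bin, AvgDailyPM25 = pm_bin,
               MaxDailyOzone = oz_bin)

  # --- outcomes from the logistic model on bins ----------------------------
  lp_for <- function(effects) {
    lp <- numeric(n_all)
    for (f in names(effects)) {
      off <- effects[[f]]
      b <- bins[[f]]
      contrib <- ifelse(is.na(b), 0, off[b])
      lp <- lp + contrib
    }
    lp
  }
  outcome_draw <- function(prev, effects) {
    lp <- lp_for(effects)
    c0 <- if (max(abs(lp)) < 1e-12) stats::qlogis(prev)
      else stats::uniroot(function(c) mean(stats::plogis(c + lp)) - prev,
                          interval = stats::qlogis(prev) + c(-6, 6),
                          tol = 1e-10)$root
    stats::runif(n_all) < stats::plogis(c0 + lp)
  }
  ed_any <- outcome_draw(config$prevalence_ed, config$effects_ed) & is_cohort
  pred_any <- outcome_draw(config$prevalence_prednisone, config$effects_prednisone) & is_cohort
  ed_count <- ifelse(ed_any, 1L + stats::rpois(n_all, 0.5), 0L)
  pred_count <- ifelse(pred_any, 1L + stats::rpois(n_all, 0.4), 0L)

  # --- raw realization ------------------------------------------------------
  patient_id <- sprintf("P%07d", seq_len(n_all))
  birth_year <- yr - (age_bin_lo[age_bin] +
                        floor(stats::runif(n_all) *
                                (age_bin_hi[age_bin] - age_bin_lo[age_bin] + 1))) - 1L
  birth_date <- as.Date(sprintf("%d-01-01", birth_year)) +
    sample.int(364L, n_all, replace = TRUE)

  # x: PM2.5 subcell strip + roadway-distance offset within a 1-km block
  pm_cell_idx <- (pm_bin - 1L) * 10L + sample.int(10L, n_all, replace = TRUE)
  pm_cell_idx[is.na(pm_bin)] <- NA
  cxmin <- pm_cells$xmin[pm_cell_idx]; cxmax <- pm_cells$xmax[pm_cell_idx]
  rb <- ifelse(is.na(road_bin), 1L, road_bin)  # placeholder; masked below
  d_target <- stats::runif(n_all, roadway_bin_lo[rb],
                           pmin(roadway_bin_hi[rb], 499.9))
  side <- stats::runif(n_all) < 0.5
  u <- ifelse(side, d_target, road_spacing - d_target)
  m_lo <- ceiling(cxmin / road_spacing)
  m_hi <- floor(cxmax / road_spacing) - 1L
  m <- m_lo + floor(stats::runif(n_all) * (m_hi - m_lo + 1))
  x <- m * road_spacing + u

  oz_cell_idx <- (ifelse(is.na(oz_bin), 1L, oz_bin) - 1L) * 10L +
    sample.int(10L, n_all, replace = TRUE)
  y <- stats::runif(n_all, oz_cells$ymin[oz_cell_idx], oz_cells$ymax[oz_cell_idx])
  x[geo_missing] <- NA; y[geo_missing] <- NA

  # block group by attribute combo (the id join is authoritative)
  key <- function(d, i5, i6) paste(d, i5, i6, sep = "|")
  bg_key <- key(ifelse(is.na(bg$density), "NA", bg$density),
                ifelse(is.na(bg$insurance_bin), "NA", bg$insurance_bin),
                ifelse(is.na(bg$income_bin), "NA", bg$income_bin))
  pat_key <- key(ifelse(is.na(dens_bin), "NA", c("rural", "urban cluster")[dens_bin]),
                 ifelse(is.na(ins_bin), "NA", ins_bin),
                 ifelse(is.na(inc_bin), "NA", inc_bin))
  blockgroup_id <- bg$blockgroup_id[match(pat_key, bg_key)]
  blockgroup_id[geo_missing] <- NA

  patients <- data.frame(
    patient_id = patient_id, birth_date = birth_date,
    sex = names(mg$sex)[sex_bin], race = names(mg$race)[race_bin],
    ethnicity = names(mg$ethnicity)[eth_bin],
    x_m = x, y_m = y, blockgroup_id = blockgroup_id,
    stringsAsFactors = FALSE
  )
  if (!is.null(covs)) patients <- cbind(patients, covs)

  encounters <- make_encounters(patient_id, is_cohort, ed_any, ed_count,
                                pred_count, yr, config)

  structure(list(
    patients = patients, encounters = encounters,
    pm25 = exposure_surface("pm25", pm_cells[, 1:5], pm_values),
    ozone = exposure_surface("ozone", oz_cells[, 1:5], oz_values),
    roadways = roadways,
    blockgroups = bg[, c("blockgroup_id", "population", "prob_no_insurance",
                         "median_income", "xmin", "xmax", "ymin", "ymax")],
    truth = list(effects_ed = config$effects_ed,
                 effects_prednisone = config$effects_prednisone,
                 bins = bins, is_cohort = is_cohort,
                 ed_count = ed_count, pred_count = pred_count),
    config = config
  ), class = "synthetic_bundle")
}

empty_bundle <- function(config, pm_cells, oz_cells, pm_values, oz_values,
                         roadways, bg) {
  structure(list(
    patients = data.frame(patient_id = character(), birth_date = as.Date(character()),
                          sex = character(), race = character(), ethnicity = character(),
                          x_m = numeric(), y_m = numeric(),
                          blockgroup_id = character(), stringsAsFactors = FALSE),
    encounters = empty_encounters(),
    pm25 = exposure_surface("pm25", pm_cells[, 1:5], pm_values),
    ozone = exposure_surface("ozone", oz_cells[, 1:5], oz_values),
    roadways = roadways,
    blockgroups = bg[, c("blockgroup_id", "population", "prob_no_insurance",
                         "median_income", "xmin", "xmax", "ymin", "ymax")],
    truth = list(effects_ed = config$effects_ed,
                 effects_prednisone = config$effects_prednisone),
    config = config
  ), class = "synthetic_bundle")
}

empty_encounters <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
             encounter_class = character(), code_type = character(),
             code = character(), stringsAsFactors = FALSE)
}

# synthetic vocabulary (configuration, not licensed terminology)
vocab <- list(
  asthma_dx = "ASTHMA",
  resp_dx = c("BRONCHITIS", "WHEEZING", "COPD", "URI"),
  pulm_dx = c("PULM_FIBROSIS", "SARCOIDOSIS", "BRONCHIECTASIS"),
  asthma_med = c("ALBUTEROL", "FLUTICASONE", "MONTELUKAST", "BUDESONIDE"),
  neb_med = "ALBUTEROL_NEB",
  asthma_proc = c("SPIROMETRY", "PEAK_FLOW", "FENO"),
  other_dx = c("HYPERTENSION", "DIABETES")
)

make_encounters <- function(patient_id, is_cohort, ed_any, ed_count,
                            pred_count, yr, config) {
  n_all <- length(patient_id)
  n_days <- as.integer(as.Date(sprintf("%d-12-31", yr)) -
                         as.Date(sprintf("%d-01-01", yr))) + 1L
  jan1 <- as.Date(sprintf("%d-01-01", yr))
  thr <- config$frequent_ed_threshold

  rule <- rep(NA_integer_, n_all)
  rule[is_cohort] <- sample.int(4L, sum(is_cohort), replace = TRUE,
                                prob = c(0.70, 0.15, 0.10, 0.05))
  rule[is_cohort & rule == 4L & !ed_any] <- 2L  # rule 4 needs in-year ED visits
  ed_count <- ifelse(!is.na(rule) & rule == 4L, pmax(ed_count, thr), ed_count)

  rows <- list()
  add <- function(pid, day, class, type, code) {
    rows[[length(rows) + 1L]] <<- data.frame(
      patient_id = pid, date = jan1 + (day - 1L), encounter_class = class,
      code_type = type, code = code, stringsAsFactors = FALSE)
  }
  rnd_day <- function(k) sample.int(n_days, k, replace = TRUE)
  pick <- function(codes, k) codes[sample.int(length(codes), k, replace = TRUE)]

  # qualifying encounters, rules 1-3 (outpatient, in-year)
  for (r in 1:3) {
    ids <- patient_id[!is.na(rule) & rule == r]
    k <- length(ids)
    if (!k) next
    if (r == 1L) {
      add(ids, rnd_day(k), "outpatient", "dx", rep(vocab$asthma_dx, k))
      add(ids, rnd_day(k), "outpatient", "med", pick(vocab$asthma_med, k))
    } else if (r == 2L) {
      add(ids, rnd_day(k), "outpatient", "dx", pick(vocab$resp_dx, k))
      add(ids, rnd_day(k), "outpatient", "med", pick(vocab$asthma_med, k))
    } else {
      add(ids, rnd_day(k), "outpatient", "dx", pick(vocab$pulm_dx, k))
      add(ids, rnd_day(k), "outpatient", "proc", pick(vocab$asthma_proc, k))
    }
  }
  # rule 4: a non-asthma respiratory dx on record (ED visits added below)
  ids4 <- patient_id[!is.na(rule) & rule == 4L]
  if (length(ids4)) {
    add(ids4, rnd_day(length(ids4)), "outpatient", "dx",
        pick(vocab$resp_dx, length(ids4)))
  }

  # outcome ED/inpatient visits with respiratory dx, distinct dates
  has_ed <- which(ed_count > 0)
  if (length(has_ed)) {
    base <- sample.int(n_days, n_all, replace = TRUE)
    idx <- rep(has_ed, ed_count[has_ed])
    j <- sequence(ed_count[has_ed])
    day <- distinct_days(base[idx], j, n_days)
    is_r4 <- !is.na(rule[idx]) & rule[idx] == 4L
    class <- ifelse(is_r4 | stats::runif(length(idx)) < 0.8, "ED", "inpatient")
    dx <- pick(c(vocab$asthma_dx, vocab$resp_dx), length(idx))
    add(patient_id[idx], day, class, "dx", dx)
    # nebulizer administration at the rule-4 ED visits
    if (any(is_r4)) {
      add(patient_id[idx][is_r4], day[is_r4], "ED", "med",
          rep(vocab$neb_med, sum(is_r4)))
    }
  }

  # prednisone prescriptions
  has_rx <- which(pred_count > 0)
  if (length(has_rx)) {
    idx <- rep(has_rx, pred_count[has_rx])
    add(patient_id[idx], rnd_day(length(idx)), "outpatient", "med",
        rep("PREDNISONE", length(idx)))
  }

  # non-cohort extras: unrelated dx; half get an asthma dx with no med
  nc <- patient_id[!is_cohort]
  if (length(nc)) {
    add(nc, rnd_day(length(nc)), "outpatient", "dx",
        pick(vocab$other_dx, length(nc)))
    half <- nc[seq_along(nc) %% 2L == 0L]
    if (length(half)) {
      add(half, rnd_day(length(half)), "outpatient", "dx",
          rep(vocab$asthma_dx, length(half)))
    }
  }

  enc <- if (length(rows)) do.call(rbind, rows) else empty_encounters()
  enc <- enc[order(enc$patient_id, enc$date, enc$code_type, enc$code), ]
  rownames(enc) <- NULL
  enc
}

#' Write / read a synthetic bundle as CSV files
#'
#' Writes the extract CSVs consumed by the downstream modules:
#' `patients.csv`, `encounters.csv`, `pm25_daily.csv` / `ozone_daily.csv`
#' (+ `pm25_cells.csv` / `ozone_cells.csv` with the cell extents),
#' `roadways.csv`, and `blockgroups.csv`. Identical bundles produce
#' byte-identical files. The returned manifest lists each path with its
#' row count.
#'
#' @param bundle a `synthetic_bundle`
#' @param directory output directory (created if needed)
#' @return `write_bundle`: data.frame manifest (`file`, `rows`),
#'   invisibly; `read_bundle`: a `synthetic_bundle` (without `truth`)
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    patients = bundle$patients, encounters = bundle$encounters,
    pm25_daily = bundle$pm25$values, pm25_cells = bundle$pm25$cells,
    ozone_daily = bundle$ozone$values, ozone_cells = bundle$ozone$cells,
    roadways = bundle$roadways, blockgroups = bundle$blockgroups
  )
  manifest <- data.frame(file = character(), rows = integer(),
                         stringsAsFactors = FALSE)
  for (nm in names(files)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    data.table::fwrite(data.table::as.data.table(files[[nm]]), path, na = "")
    manifest <- rbind(manifest, data.frame(file = path, rows = nrow(files[[nm]]),
                                           stringsAsFactors = FALSE))
  }
  jsonlite::write_json(list(study_year = bundle$config$study_year,
                            seed = bundle$config$seed,
                            n_patients = bundle$config$n_patients),
                       file.path(directory, "bundle.meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(directory) {
  rd <- function(nm, classes = NULL) {
    as.data.frame(data.table::fread(file.path(directory, paste0(nm, ".csv")),
                                    na.strings = "", colClasses = classes,
                                    data.table = FALSE))
  }
  meta <- jsonlite::read_json(file.path(directory, "bundle.meta.json"),
                              simplifyVector = TRUE)
  patients <- rd("patients")
  patients$patient_id <- as.character(patients$patient_id)
  patients$birth_date <- as.Date(patients$birth_date)
  encounters <- rd("encounters")
  if (nrow(encounters)) {
    encounters$patient_id <- as.character(encounters$patient_id)
    encounters$date <- as.Date(encounters$date)
  } else {
    encounters <- empty_encounters()
  }
  pm_v <- rd("pm25_daily"); oz_v <- rd("ozone_daily")
  structure(list(
    patients = patients, encounters = encounters,
    pm25 = exposure_surface("pm25", rd("pm25_cells"), pm_v),
    ozone = exposure_surface("ozone", rd("ozone_cells"), oz_v),
    roadways = rd("roadways"), blockgroups = rd("blockgroups"),
    truth = NULL,
    config = list(study_year = meta$study_year, seed = meta$seed,
                  n_patients = meta$n_patients)
  ), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d patients, %d encounters, study_year=%s\n",
              nrow(x$patients), nrow(x$encounters), x$config$study_year))
  invisible(x)
}
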