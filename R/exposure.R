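#' Exposure surface
#'
#' A gridded daily pollutant surface: rectangular cells plus one value per
#' (cell, date). PM2.5 cells carry daily average concentrations in ug/m3;
#' ozone cells carry daily maxima in ppb. Geometry is planar, in meters.
#'
#' @param pollutant `"pm25"` or `"ozone"`
#' @param cells data.frame `cell_id, xmin, xmax, ymin, ymax`
#' @param values data.frame `cell_id, date, value` (one row per cell-day)
#' @return object of class `exposure_surface`
#' @export
exposure_surface <- function(pollutant, cells, values) {
  pollutant <- match.arg(pollutant, c("pm25", "ozone"))
  assert_that(all(c("cell_id", "xmin", "xmax", "ymin", "ymax") %in% names(cells)),
              "cells must have cell_id, xmin, xmax, ymin, ymax")
  assert_that(all(c("cell_id", "date", "value") %in% names(values)),
              "values must have cell_id, date, value")
  assert_that(all(values$value >= 0, na.rm = TRUE), "pollutant values must be non-negative")
  if (anyDuplicated(values[, c("cell_id", "date")])) {
    abort("duplicate (cell_id, date) in surface values", "validation_error")
  }
  values$date <- as.Date(values$date)
  structure(list(pollutant = pollutant, cells = cells, values = values),
            class = "exposure_surface")
}

# Point-in-rectangle cell lookup; ties on shared edges resolve to the
# lowest cell_id. Vectorized over points. Returns cell_id or NA.
locate_cell <- function(x, y, cells) {
  n <- length(x)
  out <- rep(NA_character_, n)
  ord <- order(cells$cell_id)
  cells <- cells[ord, , drop = FALSE]
  for (i in seq_len(nrow(cells))) {
    hit <- is.na(out) & !is.na(x) & !is.na(y) &
      x >= cells$xmin[i] & x <= cells$xmax[i] &
      y >= cells$ymin[i] & y <= cells$ymax[i]
    out[hit] <- as.character(cells$cell_id[i])
  }
  out
}

annual_cell_means <- function(surface, study_year) {
  v <- surface$values
  yr <- as.integer(format(v$date, "%Y"))
  v <- v[yr == study_year, , drop = FALSE]
  if (!nrow(v)) return(stats::setNames(numeric(0), character(0)))
  agg <- tapply(v$value, as.character(v$cell_id), mean)
  stats::setNames(as.numeric(agg), names(agg))
}

annual_surface_mean <- function(geocode, surface, study_year) {
  if (length(geocode) < 2 || any(is.na(geocode[1:2]))) return(NA_real_)
  cid <- locate_cell(geocode[1], geocode[2], surface$cells)
  if (is.na(cid)) {
    log_msg("geocode outside all surface cells; exposure set to missing", level = "WARN")
    return(NA_real_)
  }
  m <- annual_cell_means(surface, study_year)
  if (!cid %in% names(m)) return(NA_real_)
  unname(m[cid])
}

#' Annual average daily PM2.5 at a geocode
#'
#' Arithmetic mean of the daily average PM2.5 values of the grid cell
#' containing the geocode, over all days of the study year present in the
#' surface (absent days are skipped, not imputed). Missing — never an
#' error — when the geocode is missing, falls outside every cell, or the
#' cell has no days in the year.
#'
#' @param geocode numeric `(x, y)` in meters, or `NA`
#' @param surface an [exposure_surface] with `pollutant == "pm25"`
#' @param study_year integer calendar year
#' @return annual mean in ug/m3, or `NA`
#' @export
annual_pm25 <- function(geocode, surface, study_year) {
  assert_that(inherits(surface, "exposure_surface") && surface$pollutant == "pm25",
              "surface must be a pm25 exposure_surface")
  annual_surface_mean(geocode, surface, study_year)
}

#' Annual mean of daily-maximum ozone at a geocode
#'
#' As [annual_pm25()], but over a surface whose daily values are daily
#' maxima in ppb.
#'
#' @inheritParams annual_pm25
#' @return annual mean of daily maxima in ppb, or `NA`
#' @export
annual_max_ozone <- function(geocode, surface, study_year) {
  assert_that(inherits(surface, "exposure_surface") && surface$pollutant == "ozone",
              "surface must be an ozone exposure_surface")
  annual_surface_mean(geocode, surface, study_year)
}

# Vectorized minimum distance from points to one segment.
point_segment_distance <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ((x - x1) * dx + (y - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  px <- x1 + t * dx; py <- y1 + t * dy
  sqrt((x - px)^2 + (y - py)^2)
}

#' Distance to the nearest major roadway
#'
#' Minimum point-to-segment Euclidean distance over all roadway segments.
#' Missing (never an error) if the segment list is empty or the geocode is
#' missing.
#'
#' @param geocode numeric `(x, y)` in meters, or `NA`
#' @param roadways data.frame `segment_id, x1, y1, x2, y2, road_class`
#' @return distance in meters, or `NA`
#' @export
roadway_distance <- function(geocode, roadways) {
  d <- roadway_distance_vec(geocode[1], geocode[2], roadways)
  d
}

# Vectorized over many points; loops over segments (few) not points (many).
roadway_distance_vec <- function(x, y, roadways) {
  n <- length(x)
  if (is.null(roadways) || !nrow(roadways)) return(rep(NA_real_, n))
  best <- rep(Inf, n)
  for (i in seq_len(nrow(roadways))) {
    d <- point_segment_distance(x, y, roadways$x1[i], roadways$y1[i],
                                roadways$x2[i], roadways$y2[i])
    best <- pmin(best, d)
  }
  best[is.na(x) | is.na(y)] <- NA_real_
  best[is.infinite(best)] <- NA_real_
  best
}

#' Residential density class from block-group population
#'
#' Census-style classification by persons per block group:
#' fewer than 2500 is rural; 2500 to 50,000 is an urban cluster; more than
#' 50,000 is urbanized.
#'
#' @param population non-negative numeric vector (persons per block group)
#' @return character vector `"rural"`, `"urban cluster"`, `"urbanized"`
#'   (`NA` propagates)
#' @export
density_class <- function(population) {
  if (any(population < 0, na.rm = TRUE)) {
    abort("population must be non-negative", "validation_error")
  }
  out <- rep(NA_character_, length(population))
  out[!is.na(population) & population < 2500] <- "rural"
  out[!is.na(population) & population >= 2500 & population <= 50000] <- "urban cluster"
  out[!is.na(population) & population > 50000] <- "urbanized"
  out
}

#' Integrate exposures for a patient roster
#'
#' Computes one [exposure estimate row][integrate_exposures] per patient
#' for the study year: annual mean PM2.5, annual mean of daily-maximum
#' ozone, distance to the nearest major roadway, residential density
#' class, and the block group's probability of no health insurance and
#' median household income. The block-group join uses `blockgroup_id`
#' when present, falling back to point-in-extent lookup from the geocode.
#' A missing geocode makes every geocode-derived field missing.
#'
#' @param patients data.frame with `patient_id, x_m, y_m, blockgroup_id`
#' @param pm25,ozone [exposure_surface] objects (either may be `NULL`)
#' @param roadways data.frame of segments (may be `NULL`/empty)
#' @param blockgroups data.frame `blockgroup_id, population,
#'   prob_no_insurance, median_income, xmin, xmax, ymin, ymax`
#' @param study_year integer calendar year
#' @return data.frame: `patient_id, study_year, avg_daily_pm25,
#'   avg_max_daily_ozone, roadway_distance, density_class,
#'   prob_no_insurance, median_income`
#' @export
integrate_exposures <- function(patients, pm25 = NULL, ozone = NULL,
                                roadways = NULL, blockgroups = NULL,
                                study_year) {
  if (anyDuplicated(patients$patient_id)) {
    abort("duplicate patient_id in roster", "validation_error")
  }
  n <- nrow(patients)
  x <- patients$x_m; y <- patients$y_m
  geo_ok <- !is.na(x) & !is.na(y)

  pm <- rep(NA_real_, n); oz <- rep(NA_real_, n)
  if (!is.null(pm25) && n) {
    means <- annual_cell_means(pm25, study_year)
    cid <- locate_cell(x, y, pm25$cells)
    pm <- unname(means[cid])
  }
  if (!is.null(ozone) && n) {
    means <- annual_cell_means(ozone, study_year)
    cid <- locate_cell(x, y, ozone$cells)
    oz <- unname(means[cid])
  }
  rd <- if (n) roadway_distance_vec(x, y, roadways) else numeric(0)

  pop <- rep(NA_real_, n); ins <- rep(NA_real_, n); inc <- rep(NA_real_, n)
  if (!is.null(blockgroups) && n) {
    bg_id <- as.character(patients$blockgroup_id %||% rep(NA_character_, n))
    bg_id[!is.na(bg_id) & !nzchar(bg_id)] <- NA_character_
    fallback <- is.na(bg_id) & geo_ok
    if (any(fallback) && all(c("xmin", "xmax", "ymin", "ymax") %in% names(blockgroups))) {
      cells <- data.frame(cell_id = blockgroups$blockgroup_id,
                          xmin = blockgroups$xmin, xmax = blockgroups$xmax,
                          ymin = blockgroups$ymin, ymax = blockgroups$ymax)
      bg_id[fallback] <- locate_cell(x[fallback], y[fallback], cells)
    }
    i <- match(bg_id, as.character(blockgroups$blockgroup_id))
    pop <- blockgroups$population[i]
    ins <- blockgroups$prob_no_insurance[i]
    inc <- blockgroups$median_income[i]
  }

  # missingness propagation: nothing geocode-derived survives a missing geocode
  pm[!geo_ok] <- NA_real_; oz[!geo_ok] <- NA_real_; rd[!geo_ok] <- NA_real_

  data.frame(patient_id = patients$patient_id,
             study_year = rep(as.integer(study_year), n),
             avg_daily_pm25 = pm, avg_max_daily_ozone = oz,
             roadway_distance = rd,
             density_class = density_class(pop),
             prob_no_insurance = ins, median_income = inc,
             stringsAsFactors = FALSE)
}
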