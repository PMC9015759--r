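# Shared fixtures and independent oracles. Oracles are deliberately
# implemented from first principles, not via the package's code paths.

# Direct-formula Pearson chi-square: sum((O - E)^2 / E), E from marginals.
chisq_oracle <- function(m) {
  m <- as.matrix(m)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  list(statistic = sum((m - E)^2 / E),
       df = (nrow(m) - 1) * (ncol(m) - 1),
       p_value = stats::pchisq(sum((m - E)^2 / E),
                               (nrow(m) - 1) * (ncol(m) - 1),
                               lower.tail = FALSE))
}

# Type-7 quantile implemented independently from sorted order statistics.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# A small hand-buildable feature table.
tiny_table <- function(n = 12, seed = 7) {
  set.seed(seed)
  rows <- data.frame(
    row_key = sprintf("R%03d", 1:n),
    Color = sample(c("red", "blue"), n, replace = TRUE),
    Size = sample(c("small", "medium", "large"), n, replace = TRUE),
    Visits = rpois(n, 1),
    stringsAsFactors = FALSE
  )
  feature_table(
    study_year = 2016,
    schema = list(
      list(name = "row_key", kind = "categorical", labels = character()),
      list(name = "Color", kind = "categorical", labels = c("red", "blue")),
      list(name = "Size", kind = "binned_ordinal",
           labels = c("small", "medium", "large")),
      list(name = "Visits", kind = "count", labels = character())
    ),
    rows = rows
  )
}

# Random non-degenerate r x c count table.
random_table <- function(r, c, n = 500) {
  repeat {
    m <- matrix(stats::rmultinom(1, n, prob = runif(r * c, 0.2, 1)), nrow = r)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Raw patient frame covering every default scheme, for deidentify tests.
random_raw_frame <- function(n, seed = 99, year = 2016) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P%05d", 1:n),
    birth_date = as.Date(sprintf("%d-01-01", year)) -
      sample(400:(89 * 365), n, replace = TRUE),
    Sex = sample(c("male", "female"), n, replace = TRUE),
    Race = sample(c("Caucasian", "African American", "Unknown/other"),
                  n, replace = TRUE),
    Ethnicity = sample(c("Hispanic", "Not Hispanic", "Unknown"), n, replace = TRUE),
    ResidentialDensity = sample(c("rural", "urban cluster", NA), n, replace = TRUE),
    ProbNoInsurance = ifelse(runif(n) < 0.1, NA, runif(n, 0, 0.5548)),
    MedianIncome = ifelse(runif(n) < 0.1, NA, runif(n, 7470, 250001)),
    RoadwayDistance = ifelse(runif(n) < 0.1, NA, runif(n, 0, 2000)),
    AvgDailyPM25 = ifelse(runif(n) < 0.1, NA, runif(n, 3.27, 10.83)),
    MaxDailyOzone = ifelse(runif(n) < 0.1, NA, runif(n, 27.80, 46.45)),
    TotalEDInpatientVisits = rpois(n, 0.3),
    TotalPrednisoneRx = rpois(n, 0.2),
    stringsAsFactors = FALSE
  )
}

# Independent per-row interval membership: first interval closed both ends,
# later ones (a, b]; or all [a, b) when left_closed.
rebin_oracle <- function(value, edges, labels, left_closed = FALSE) {
  if (is.na(value)) return(NA_character_)
  k <- length(edges) - 1
  for (i in seq_len(k)) {
    lo <- edges[i]; hi <- edges[i + 1]
    inside <- if (left_closed) {
      value >= lo && (value < hi || (i == k && is.infinite(hi)))
    } else if (i == 1) {
      value >= lo && value <= hi
    } else {
      value > lo && value <= hi
    }
    if (inside) return(labels[i])
  }
  NA_character_
}
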