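#' @import data.table
#' @importFrom stats quantile pchisq chisq.test rbinom rpois runif plogis qlogis uniroot setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "opencohort_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(ok, msg, class = "validation_error") {
  if (!isTRUE(ok)) abort(msg, class)
  invisible(TRUE)
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used when printing percentages in cohort summary tables
#' (base R `round()` rounds half to even).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# FNV-1a 32-bit hash over a string; used for stable, opaque cohort ids.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), b)
    # multiply by 16777619 mod 2^32 using split arithmetic to stay in doubles
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

# Deterministic per-purpose substream seed derived from a master seed.
derive_seed <- function(seed, label) {
  h <- strtoi(substr(fnv1a(paste0(label, ":", seed)), 1, 7), 16L)
  (h %% 2147483640L) + 1L
}

log_msg <- function(..., level = "INFO") {
  if (isTRUE(getOption("opencohort.quiet", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}
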