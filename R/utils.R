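#' @importFrom rlang .data
#' @importFrom stats lm predict quantile rnorm runif sd setNames qnbinom qpois median
#' @importFrom utils head tail
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream child seed from one master seed; stays < 2^31.
child_seed <- function(seed, stream) {
  offset <- c(
    members = 101L, tracts = 211L, covariates = 307L, visits = 401L,
    fit = 503L, bootstrap = 601L
  )[[stream]]
  (as.integer(seed) %% 2000000000L) + offset
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' US federal holidays plus the winter holiday block
#'
#' Returns the federal holiday calendar used by both the synthetic generator
#' and the counterfactual model's holiday indicator: New Year's Day, Martin
#' Luther King Jr. Day, Presidents' Day, Memorial Day, Juneteenth,
#' Independence Day, Labor Day, Columbus Day, Veterans Day, Thanksgiving and
#' Christmas, plus every day from December 24 through January 1. Daily visit
#' series dip sharply on these days, and a pre-period spanning two winter
#' holiday seasons forces any counterfactual model to learn the dip.
#'
#' @param years Integer vector of calendar years.
#' @return Sorted `Date` vector of holiday dates (deduplicated).
#' @examples
#' us_holidays(2024)
#' @export
us_holidays <- function(years) {
  nth_weekday <- function(year, month, wday, n) {
    d <- seq(as.Date(sprintf("%d-%02d-01", year, month)), by = "day", length.out = 31)
    d <- d[as.POSIXlt(d)$wday == wday & as.POSIXlt(d)$mon == month - 1]
    if (n > 0) d[n] else d[length(d) + 1 + n]
  }
  out <- lapply(years, function(y) {
    c(
      as.Date(sprintf("%d-01-01", y)),
      nth_weekday(y, 1, 1, 3),          # MLK: 3rd Monday of January
      nth_weekday(y, 2, 1, 3),          # Presidents' Day
      nth_weekday(y, 5, 1, -1),         # Memorial Day: last Monday of May
      as.Date(sprintf("%d-06-19", y)),  # Juneteenth
      as.Date(sprintf("%d-07-04", y)),
      nth_weekday(y, 9, 1, 1),          # Labor Day
      nth_weekday(y, 10, 1, 2),         # Columbus Day
      as.Date(sprintf("%d-11-11", y)),  # Veterans Day
      nth_weekday(y, 11, 4, 4),         # Thanksgiving: 4th Thursday
      as.Date(sprintf("%d-12-25", y)),
      seq(as.Date(sprintf("%d-12-24", y)), as.Date(sprintf("%d-12-31", y)), by = "day"),
      as.Date(sprintf("%d-01-01", y + 1))
    )
  })
  sort(unique(do.call(c, out)))
}

is_holiday <- function(dates) {
  yrs <- sort(unique(as.POSIXlt(dates)$year + 1900L))
  dates %in% us_holidays(c(yrs[1] - 1L, yrs))
}

# ISO week label "GGGG-WVV" used for weekly (wastewater) covariates.
iso_week <- function(dates) format(dates, "%G-W%V")

exposure_levels <- function() c("high", "moderate", "minimal")
setting_levels <- function() c("outpatient", "virtual")
cause_levels <- function() {
  c("all_cause", "cardiovascular", "injury", "neuropsychiatric", "respiratory")
}
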