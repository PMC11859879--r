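## Calendar helpers. All diary arithmetic uses integer day offsets from
## 1 January of the observation year (day 0); intervals are half-open
## [start, end). Offsets may be negative (prior-year dispensings).

year_start <- function(year) as.Date(sprintf("%d-01-01", year))

#' Number of days in a calendar year
#' @param year calendar year
#' @return 365 or 366
#' @keywords internal
year_length <- function(year) {
  as.integer(year_start(year + 1L) - year_start(year))
}

#' Convert calendar dates to day offsets
#'
#' Day 0 is 1 January of `year`; dates before that map to negative
#' offsets.
#'
#' @param dates a `Date` vector (or ISO-8601 strings)
#' @param year observation year defining day 0
#' @return integer vector of offsets
#' @export
day_offset <- function(dates, year) {
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  as.integer(dates - year_start(year))
}

#' Convert day offsets back to calendar dates
#' @param offsets integer day offsets (day 0 = 1 Jan of `year`)
#' @param year observation year
#' @return `Date` vector
#' @export
offset_date <- function(offsets, year) {
  year_start(year) + as.integer(offsets)
}

#' Calendar windows of an observation year
#'
#' Returns the half-open day-offset bounds of the calendar windows of
#' one year: 12 months, 4 quarters (Q1 = Jan-Mar, ...), or the single
#' annual window.
#'
#' @param granularity one of `"ANNUAL"`, `"QUARTER"`, `"MONTH"`
#' @param year observation year
#' @return `data.table` with columns `window` (1-based index), `start_day`,
#'   `end_day`
#' @export
window_bounds <- function(granularity = c("ANNUAL", "QUARTER", "MONTH"),
                          year = 2017L) {
  granularity <- match.arg(granularity)
  yl <- year_length(year)
  if (granularity == "ANNUAL") {
    return(data.table(window = 1L, start_day = 0L, end_day = yl))
  }
  month_starts <- day_offset(seq(year_start(year), by = "month",
                                 length.out = 12L), year)
  edges <- c(month_starts, yl)
  if (granularity == "MONTH") {
    data.table(window = 1:12, start_day = edges[1:12],
               end_day = edges[2:13])
  } else {
    q <- seq(1L, 13L, by = 3L)
    data.table(window = 1:4, start_day = edges[q[1:4]],
               end_day = edges[q[2:5]])
  }
}

n_windows <- function(granularity) {
  switch(granularity, ANNUAL = 1L, QUARTER = 4L, MONTH = 12L)
}

#' Completed age in years at a reference date
#' @param birth_date,ref_date `Date` vectors
#' @return integer years
#' @export
age_at <- function(birth_date, ref_date) {
  if (!inherits(birth_date, "Date")) birth_date <- as.Date(birth_date)
  if (!inherits(ref_date, "Date")) ref_date <- as.Date(ref_date)
  by <- as.integer(format(birth_date, "%Y"))
  ry <- as.integer(format(ref_date, "%Y"))
  ## subtract one if the birthday has not yet occurred in the ref year
  before <- format(ref_date, "%m%d") < format(birth_date, "%m%d")
  as.integer(ry - by - before)
}

## round half up to `digits` decimals (the convention of printed
## percentage tables); a tiny epsilon guards against representation
## error in values like 2.675 stored as 2.67499...
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
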