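#' Days of supply of a dispensing from its DDD content
#'
#' One defined daily dose (DDD) covers one day of therapy, so a
#' dispensing of `n_packages` packages each containing
#' `ddd_per_package` DDDs covers `n_packages * ddd_per_package` days.
#' Fractional totals are rounded (half up by default) and floored at
#' one day: any dispensing covers at least the dispensing day.
#'
#' @param n_packages positive integer vector, packages dispensed
#' @param ddd_per_package positive numeric vector, DDDs per package
#' @param rounding how to resolve fractional day totals: `"round"`
#'   (half up), `"floor"`, or `"ceil"`
#' @return integer vector of covered days (>= 1)
#' @examples
#' days_supply(2, 28)    # 56
#' days_supply(1, 0.4)   # 1 (floor at one day)
#' days_supply(3, 16.5)  # 50 (49.5 rounds half up)
#' @export
days_supply <- function(n_packages, ddd_per_package,
                        rounding = c("round", "floor", "ceil")) {
  rounding <- match.arg(rounding)
  if (any(n_packages <= 0) || any(ddd_per_package <= 0)) {
    stop("`n_packages` and `ddd_per_package` must be positive")
  }
  x <- n_packages * ddd_per_package
  d <- switch(rounding,
    round = floor(x + 0.5 + sqrt(.Machine$double.eps)),
    floor = floor(x),
    ceil  = ceiling(x)
  )
  as.integer(pmax(1, d))
}

#' ATC fourth-level (chemical subgroup) class of an ATC code
#'
#' The first five characters of an ATC code (e.g. `C10AA` from
#' `C10AA05`). Drugs sharing this class are treated as interchangeable
#' when chaining refills.
#'
#' @param atc_code character vector of ATC codes (>= 5 characters)
#' @return character vector of 5-character class codes
#' @export
atc_level4 <- function(atc_code) {
  if (any(nchar(atc_code) < 5L)) {
    stop("ATC codes must have at least 5 characters")
  }
  toupper(substr(atc_code, 1L, 5L))
}

#' Build per-patient supply diaries from refill records
#'
#' Converts a refill table into non-overlapping coverage intervals per
#' patient and ATC fourth-level class. Within a class, refills are
#' processed in dispensing order (ties broken by `record_id`); when a
#' refill arrives before the previous coverage of the same class has
#' ended, its whole coverage period is shifted to start the day after
#' that coverage ends, so supply is banked rather than double-counted
#' or lost. Coverage across different classes may overlap freely.
#'
#' Dispensings from the year before `observation_year` take part in the
#' chaining, so prior-year supply shifted forward can cover days of the
#' observation year; use [clip_diary()] to restrict the result to the
#' year afterwards.
#'
#' @param refills `data.frame`/`data.table` with columns `patient_id`,
#'   `dispense_date` (`Date` or ISO-8601 string), `atc_code`,
#'   `n_packages`, `ddd_per_package`, and optionally `record_id`
#'   (tie-break ordinal; defaults to input row order)
#' @param observation_year calendar year defining day 0 of the diary
#' @param rounding passed to [days_supply()]
#' @param max_shift_days optional cap on how far a refill may be shifted
#'   past its dispensing date (`Inf`, the default, never truncates
#'   banked supply)
#' @return a `supply_diary`: a `data.table` with one row per refill —
#'   `patient_id`, `atc4`, `start_day`, `end_day` (half-open offsets
#'   from 1 Jan of `observation_year`), `record_id` — sorted and
#'   non-overlapping within each `patient_id` x `atc4`. Attributes
#'   `observation_year` and `rounding` record the construction.
#' @examples
#' rf <- data.frame(patient_id = "p1",
#'                  dispense_date = as.Date("2017-01-01") + c(0, 20),
#'                  atc_code = "C10AA05", n_packages = 1,
#'                  ddd_per_package = 30)
#' build_supply_diary(rf)  # segments [0,30) and [30,60)
#' @export
build_supply_diary <- function(refills, observation_year = 2017L,
                               rounding = c("round", "floor", "ceil"),
                               max_shift_days = Inf) {
  rounding <- match.arg(rounding)
  rf <- validate_refills(refills)
  rf[, day := day_offset(dispense_date, observation_year)]
  rf[, atc4 := atc_level4(atc_code)]
  rf[, days := days_supply(n_packages, ddd_per_package, rounding)]
  setorder(rf, patient_id, atc4, day, record_id)
  ## end_i = max(day_i, end_{i-1}) + days_i unrolls to
  ## end_i = cummax(day_j - cumsum_{j-1}(days)) + cumsum_i(days),
  ## which vectorises the shift rule within each class chain
  if (is.infinite(max_shift_days)) {
    rf[, cs := cumsum(as.numeric(days)), by = .(patient_id, atc4)]
    rf[, end_day := cummax(day - (cs - days)) + cs, by = .(patient_id, atc4)]
    rf[, start_day := end_day - days]
  } else {
    ## with a stockpiling cap the chain is genuinely sequential: a
    ## refill whose shifted start would exceed dispense + cap is
    ## discarded entirely, leaving the running end untouched
    chain_capped <- function(day, days) {
      n <- length(day)
      s <- e <- rep(NA_real_, n)
      cur <- -Inf
      for (i in seq_len(n)) {
        st <- max(day[i], cur)
        if (st <= day[i] + max_shift_days) {
          s[i] <- st
          e[i] <- st + days[i]
          cur <- e[i]
        }
      }
      list(s, e)
    }
    rf[, c("start_day", "end_day") := chain_capped(day, days),
       by = .(patient_id, atc4)]
    rf <- rf[!is.na(start_day)]
  }
  out <- rf[, .(patient_id, atc4, start_day = as.integer(start_day),
                end_day = as.integer(end_day), record_id)]
  setattr(out, "observation_year", as.integer(observation_year))
  setattr(out, "rounding", rounding)
  setattr(out, "class", c("supply_diary", class(out)))
  out[]
}

diary_year <- function(diary) {
  y <- attr(diary, "observation_year")
  if (is.null(y)) stop("not a supply_diary: missing observation_year")
  y
}

#' Clip a supply diary to a period
#'
#' Intersects every coverage segment with `[period_start, period_end)`
#' and drops segments that become empty. A prior-year dispensing whose
#' shifted coverage reaches into the period survives with the portion
#' inside it.
#'
#' @param diary a [build_supply_diary()] result
#' @param period_start,period_end day offsets (integers) or `Date`s;
#'   default the whole observation year
#' @return a clipped `supply_diary`
#' @export
clip_diary <- function(diary, period_start = NULL, period_end = NULL) {
  year <- diary_year(diary)
  if (is.null(period_start)) period_start <- 0L
  if (is.null(period_end)) period_end <- year_length(year)
  if (inherits(period_start, "Date")) period_start <- day_offset(period_start, year)
  if (inherits(period_end, "Date")) period_end <- day_offset(period_end, year)
  if (period_end < period_start) stop("`period_end` must be >= `period_start`")
  out <- as.data.table(diary)[end_day > period_start & start_day < period_end]
  out[, `:=`(start_day = pmax(start_day, as.integer(period_start)),
             end_day = pmin(end_day, as.integer(period_end)))]
  setattr(out, "observation_year", year)
  setattr(out, "rounding", attr(diary, "rounding"))
  setattr(out, "class", c("supply_diary", class(out)))
  out[]
}

#' Covered days of one class within a calendar window
#'
#' Counts the days of a window that fall inside any coverage segment of
#' the given ATC fourth-level class. A class absent from the diary
#' simply has zero covered days.
#'
#' @param diary a `supply_diary`
#' @param atc4 single 5-character class code
#' @param granularity `"ANNUAL"`, `"QUARTER"` or `"MONTH"`
#' @param window 1-based window index within the year
#' @return `data.table` with `patient_id` and integer `days` for every
#'   patient in the diary (zero rows included)
#' @export
covered_days <- function(diary, atc4, granularity = "ANNUAL", window = 1L) {
  year <- diary_year(diary)
  wb <- window_bounds(granularity, year)
  if (!window %in% wb$window) stop("no such window for this granularity")
  ws <- wb$start_day[window]
  we <- wb$end_day[window]
  cls <- atc4
  dt <- as.data.table(diary)
  hit <- dt[atc4 == cls,
            .(days = sum(pmax(0L, pmin(end_day, we) - pmax(start_day, ws)))),
            by = patient_id]
  base <- unique(dt[, .(patient_id)])
  out <- hit[base, on = "patient_id"]
  out[is.na(days), days := 0L]
  setorder(out, patient_id)
  out[]
}

## ---- input validation ------------------------------------------------

validate_refills <- function(refills) {
  need <- c("patient_id", "dispense_date", "atc_code", "n_packages",
            "ddd_per_package")
  miss <- setdiff(need, names(refills))
  if (length(miss)) {
    stop("refill table is missing column(s): ", paste(miss, collapse = ", "))
  }
  rf <- as.data.table(refills)
  if (!"record_id" %in% names(rf)) rf[, record_id := seq_len(.N)]
  rf <- copy(rf[, c(need, "record_id"), with = FALSE])
  if (!identical(class(rf$dispense_date), "Date")) {
    rf[, dispense_date := as.Date(dispense_date)]
  }
  if (anyNA(rf$dispense_date)) stop("unparseable dispense_date values")
  if (any(rf$n_packages <= 0) || any(rf$ddd_per_package <= 0)) {
    stop("`n_packages` and `ddd_per_package` must be positive")
  }
  rf
}
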