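## ATC level-1/level-2 groups usually dispensed for short-term
## treatments (stomatologicals, laxatives, systemic anti-infectives and
## vaccines, ectoparasiticides, dermatologicals, various): these are
## excluded by the Chronic ATC definition.
SHORT_TERM_ATC_PREFIXES <- c("A01", "A06", "J01", "J02", "J05", "J06",
                             "J07", "P03", "D", "V")

#' Specify an operational polypharmacy definition
#'
#' Three drug-inclusion rules determine which ATC fourth-level classes
#' enter the polypharmacy count:
#' * `ALL_ATC` — every dispensed class counts;
#' * `CHRONIC_ATC` — classes in ATC groups usually associated with
#'   short-term treatments are excluded (by default the level-2 groups
#'   A01, A06, J01, J02, J05, J06, J07, P03 and the level-1 groups D
#'   and V);
#' * `DDD_GE_60` — only classes with cumulative annual DDDs of at
#'   least 60 count.
#'
#' @param name one of `"ALL_ATC"`, `"CHRONIC_ATC"`, `"DDD_GE_60"`
#' @param excluded_atc_prefixes prefix list override for `CHRONIC_ATC`
#' @param annual_ddd_threshold threshold override for `DDD_GE_60`
#' @return a `definition_spec` list
#' @export
definition_spec <- function(name = c("ALL_ATC", "CHRONIC_ATC", "DDD_GE_60"),
                            excluded_atc_prefixes = NULL,
                            annual_ddd_threshold = NULL) {
  name <- match.arg(name)
  spec <- list(
    name = name,
    excluded_atc_prefixes = switch(name,
      CHRONIC_ATC = excluded_atc_prefixes %||% SHORT_TERM_ATC_PREFIXES,
      character(0)),
    annual_ddd_threshold = switch(name,
      DDD_GE_60 = annual_ddd_threshold %||% 60,
      0)
  )
  structure(spec, class = "definition_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cumulative annual DDDs per patient and ATC fourth-level class
#'
#' Sums the dispensed DDD content (`n_packages * ddd_per_package`, not
#' rounded to days) of every refill contributing at least one covered
#' day to the observation year, consistent with the cohort-entry rule
#' that admits prior-year dispensings whose shifted coverage reaches
#' the year. With `attribution = "dispensed"` the sum is instead over
#' refills dispensed within the year, regardless of coverage.
#'
#' @param refills refill table (see [build_supply_diary()])
#' @param diary the diary built from `refills` (needed to decide which
#'   refills cover days of the year under `"covered"` attribution)
#' @param observation_year calendar year
#' @param attribution `"covered"` (default) or `"dispensed"`
#' @return `data.table` with `patient_id`, `atc4`, `total_ddds`
#' @export
annual_ddd_totals <- function(refills, diary = NULL,
                              observation_year = 2017L,
                              attribution = c("covered", "dispensed")) {
  attribution <- match.arg(attribution)
  rf <- validate_refills(refills)
  rf[, atc4 := atc_level4(atc_code)]
  if (attribution == "covered") {
    if (is.null(diary)) {
      diary <- build_supply_diary(rf, observation_year)
    }
    yl <- year_length(diary_year(diary))
    in_year <- as.data.table(diary)[end_day > 0L & start_day < yl,
                                    .(patient_id, record_id)]
    rf <- rf[in_year, on = c("patient_id", "record_id")]
  } else {
    rf[, day := day_offset(dispense_date, observation_year)]
    rf <- rf[day >= 0L & day < year_length(observation_year)]
  }
  out <- rf[, .(total_ddds = sum(n_packages * ddd_per_package)),
            by = .(patient_id, atc4)]
  setorder(out, patient_id, atc4)
  out[]
}

#' Restrict a supply diary to the classes a definition counts
#'
#' `ALL_ATC` returns the diary unchanged; `CHRONIC_ATC` drops every
#' class whose code starts with an excluded ATC level-1/2 prefix;
#' `DDD_GE_60` drops classes whose cumulative annual DDDs fall below
#' the threshold.
#'
#' @param diary a `supply_diary`
#' @param spec a [definition_spec()]
#' @param ddd_totals [annual_ddd_totals()] output; required for
#'   `DDD_GE_60`
#' @return the filtered `supply_diary`
#' @export
apply_definition <- function(diary, spec, ddd_totals = NULL) {
  stopifnot(inherits(spec, "definition_spec"))
  dt <- as.data.table(diary)
  out <- switch(spec$name,
    ALL_ATC = dt,
    CHRONIC_ATC = {
      drop <- Reduce(`|`, lapply(spec$excluded_atc_prefixes,
                                 function(p) startsWith(dt$atc4, p)),
                     accumulate = FALSE)
      if (is.null(drop)) dt else dt[!drop]
    },
    DDD_GE_60 = {
      if (is.null(ddd_totals)) {
        stop("`ddd_totals` is required for the DDD_GE_60 definition")
      }
      keep_dt <- as.data.table(ddd_totals)[
        total_ddds >= spec$annual_ddd_threshold, .(patient_id, atc4)]
      dt[keep_dt, on = c("patient_id", "atc4"), nomatch = NULL]
    }
  )
  setattr(out, "observation_year", attr(diary, "observation_year"))
  setattr(out, "rounding", attr(diary, "rounding"))
  if (!inherits(out, "supply_diary")) {
    setattr(out, "class", c("supply_diary", class(out)))
  }
  out[]
}
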