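#' Window scheme for polypharmacy assessment
#'
#' Bundles the time-window granularity with the rule aggregating the
#' per-window drug counts into one patient-level summary:
#' * `MAX` — the maximum count over the 12 months or 4 quarters (the
#'   primary rule);
#' * `MEAN` — the unrounded arithmetic mean compared with the same
#'   thresholds;
#' * `COVERED_FRACTION` — on-polypharmacy only if at least
#'   `ceiling(covered_fraction * n_windows)` windows reach the drug
#'   threshold (0.5/0.8/1.0 on months = 6, 10, or 12 months).
#'
#' @param granularity `"ANNUAL"`, `"QUARTER"` or `"MONTH"`
#' @param aggregation `"MAX"`, `"MEAN"` or `"COVERED_FRACTION"`
#' @param covered_fraction required fraction of windows in (0, 1]
#'   (only for `COVERED_FRACTION`)
#' @return a `window_scheme` list
#' @export
window_scheme <- function(granularity = c("ANNUAL", "QUARTER", "MONTH"),
                          aggregation = c("MAX", "MEAN", "COVERED_FRACTION"),
                          covered_fraction = NULL) {
  granularity <- match.arg(granularity)
  aggregation <- match.arg(aggregation)
  if (aggregation == "COVERED_FRACTION") {
    if (is.null(covered_fraction) || covered_fraction <= 0 ||
        covered_fraction > 1) {
      stop("`covered_fraction` must be in (0, 1]")
    }
  } else {
    covered_fraction <- NA_real_
  }
  structure(list(granularity = granularity, aggregation = aggregation,
                 covered_fraction = covered_fraction),
            class = "window_scheme")
}

POLY_BIN_LEVELS <- c("1-4", "5", "6", "7", "8", "9", ">=10")

## bin a (possibly fractional) drug count; counts of zero fall in the
## reference bin
bin_count <- function(x) {
  cut(x, breaks = c(-Inf, 5, 6, 7, 8, 9, 10, Inf), right = FALSE,
      labels = c(POLY_BIN_LEVELS[1:6], POLY_BIN_LEVELS[7]))
}

#' Distinct drug classes covered per calendar window
#'
#' For each patient and each window of the observation year, counts the
#' distinct ATC fourth-level classes with at least one covered day in
#' that window.
#'
#' @param diary a `supply_diary`, normally clipped to the observation
#'   year with [clip_diary()]
#' @param granularity `"ANNUAL"`, `"QUARTER"` or `"MONTH"`
#' @param patients optional character vector of patient ids defining
#'   the complete grid (patients without coverage get zero counts);
#'   defaults to the patients present in the diary
#' @return `data.table` with `patient_id`, `window`, `n_classes`, one
#'   row per patient and window
#' @export
count_per_window <- function(diary, granularity = "ANNUAL",
                             patients = NULL) {
  year <- diary_year(diary)
  wb <- window_bounds(granularity, year)
  dt <- as.data.table(diary)
  if (is.null(patients)) patients <- unique(dt$patient_id)
  pieces <- lapply(seq_len(nrow(wb)), function(i) {
    ws <- wb$start_day[i]; we <- wb$end_day[i]
    hit <- unique(dt[end_day > ws & start_day < we,
                     .(patient_id, atc4)])
    hit[, .(window = wb$window[i], n_classes = .N), by = patient_id]
  })
  counts <- rbindlist(pieces)
  grid <- CJ(patient_id = patients, window = wb$window, unique = TRUE)
  out <- counts[grid, on = c("patient_id", "window")]
  out[is.na(n_classes), n_classes := 0L]
  setorder(out, patient_id, window)
  out[]
}

#' Distinct classes dispensed per window (no-coverage counting)
#'
#' The sensitivity-analysis counterpart of [count_per_window()]: a
#' class counts in a window only if a refill was dispensed in that
#' window, ignoring both coverage duration and same-class overlap
#' shifting.
#'
#' @param refills refill table
#' @param granularity `"ANNUAL"`, `"QUARTER"` or `"MONTH"`
#' @param observation_year calendar year
#' @param patients optional complete patient grid, as in
#'   [count_per_window()]
#' @return `data.table` with `patient_id`, `window`, `n_classes`
#' @export
count_dispensed_per_window <- function(refills, granularity = "ANNUAL",
                                       observation_year = 2017L,
                                       patients = NULL) {
  rf <- validate_refills(refills)
  rf[, atc4 := atc_level4(atc_code)]
  rf[, day := day_offset(dispense_date, observation_year)]
  wb <- window_bounds(granularity, observation_year)
  if (is.null(patients)) patients <- unique(rf$patient_id)
  rf <- rf[day >= 0L & day < year_length(observation_year)]
  rf[, window := findInterval(day, wb$start_day)]
  counts <- unique(rf[, .(patient_id, window, atc4)])[
    , .(n_classes = .N), by = .(patient_id, window)]
  grid <- CJ(patient_id = patients, window = wb$window, unique = TRUE)
  out <- counts[grid, on = c("patient_id", "window")]
  out[is.na(n_classes), n_classes := 0L]
  setorder(out, patient_id, window)
  out[]
}

#' Aggregate per-window counts into patient polypharmacy status
#'
#' @param counts output of [count_per_window()] or
#'   [count_dispensed_per_window()] (complete patient x window grid)
#' @param scheme a [window_scheme()]; its granularity must match the
#'   number of windows in `counts`
#' @return `data.table` with `patient_id`, `summary_count` (maximum or
#'   unrounded mean over windows), `class_bin` (`1-4`, `5`, ..., `>=10`),
#'   and logical `poly5` / `poly10` flags. Under `COVERED_FRACTION`
#'   the flags follow the qualifying-window rule and `summary_count` /
#'   `class_bin` report the maximum.
#' @export
summarize_counts <- function(counts, scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  cnt <- as.data.table(counts)
  nw <- n_windows(scheme$granularity)
  wpp <- cnt[, .N, by = patient_id]
  if (any(wpp$N != nw)) {
    stop("`counts` must have exactly ", nw,
         " windows per patient for granularity ", scheme$granularity)
  }
  out <- switch(scheme$aggregation,
    MAX = cnt[, .(summary_count = as.numeric(max(n_classes))),
              by = patient_id][
      , `:=`(poly5 = summary_count >= 5, poly10 = summary_count >= 10)],
    MEAN = cnt[, .(summary_count = mean(n_classes)), by = patient_id][
      , `:=`(poly5 = summary_count >= 5, poly10 = summary_count >= 10)],
    COVERED_FRACTION = {
      need <- ceiling(scheme$covered_fraction * nw)
      cnt[, .(summary_count = as.numeric(max(n_classes)),
              poly5 = sum(n_classes >= 5L) >= need,
              poly10 = sum(n_classes >= 10L) >= need),
          by = patient_id]
    }
  )
  out[, class_bin := bin_count(summary_count)]
  setcolorder(out, c("patient_id", "summary_count", "class_bin",
                     "poly5", "poly10"))
  setorder(out, patient_id)
  out[]
}

#' Polypharmacy prevalence in a cohort
#'
#' @param statuses [summarize_counts()] output, one row per cohort
#'   patient
#' @param flag `"poly5"`, `"poly10"`, or one of the class-bin labels
#'   (`"1-4"`, `"5"`, ..., `">=10"`)
#' @return list with `count`, `n`, `proportion`, and `percent` (the
#'   proportion as a percentage rounded half-up to 2 decimals, the
#'   convention of printed prevalence tables)
#' @export
prevalence <- function(statuses, flag = "poly5") {
  st <- as.data.table(statuses)
  if (nrow(st) == 0L) stop("empty cohort")
  count <- if (flag %in% c("poly5", "poly10")) {
    sum(st[[flag]])
  } else if (flag %in% POLY_BIN_LEVELS) {
    sum(st$class_bin == flag)
  } else {
    stop("unknown flag: ", flag)
  }
  list(count = count, n = nrow(st), proportion = count / nrow(st),
       percent = prevalence_pct(count, nrow(st)))
}

#' Percentage of a count over a cohort size, as printed
#'
#' `100 * count / n` rounded half-up to two decimals — the arithmetic
#' behind every percentage in a prevalence table.
#'
#' @param count,n nonnegative counts, `n > 0`
#' @return numeric percentage
#' @examples
#' prevalence_pct(91337, 431620)  # 21.16
#' @export
prevalence_pct <- function(count, n) {
  stopifnot(all(n > 0))
  round_half_up(100 * count / n, 2L)
}

#' Patient distribution over polypharmacy classes
#'
#' @param statuses [summarize_counts()] output
#' @return `data.table` with `class_bin`, `count` and `percent` (all
#'   bins present, zero counts included)
#' @export
prevalence_by_class <- function(statuses) {
  st <- as.data.table(statuses)
  if (nrow(st) == 0L) stop("empty cohort")
  tab <- st[, .(count = .N), by = class_bin]
  full <- data.table(class_bin = factor(POLY_BIN_LEVELS,
                                        levels = POLY_BIN_LEVELS))
  out <- tab[full, on = "class_bin"]
  out[is.na(count), count := 0L]
  out[, percent := prevalence_pct(count, nrow(st))]
  out[]
}
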