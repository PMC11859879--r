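#' Drop short hospital stays
#'
#' Keeps only admissions strictly longer than `min_days` (a stay of
#' exactly `min_days` is dropped), for sensitivity analyses restricted
#' to the more severe hospitalizations.
#'
#' @param discharges discharge table with `patient_id`,
#'   `admission_date`, `discharge_date`
#' @param min_days stays must exceed this length in days (default 7)
#' @return the filtered discharge table
#' @export
long_stay_filter <- function(discharges, min_days = 7L) {
  dc <- validate_discharges(discharges)
  dc[as.integer(discharge_date - admission_date) > min_days]
}

#' Assemble the hospitalization-outcome cohort
#'
#' Joins the assisted-residents registry, the hospital discharge
#' records, and per-patient polypharmacy statuses into analysis-ready
#' rows. The outcome is any admission inside the outcome window
#' (default the first half of the year after the observation year).
#' Two exclusions guard the outcome classification:
#' * patients who die before the end of the outcome year
#'   (`died_before_end_period`), since the cohort is restricted to
#'   patients alive through it;
#' * patients with no admission in the first half of the outcome year
#'   but at least one in the second half
#'   (`second_half_only_hospitalization`), to avoid misclassifying
#'   soon-to-be-hospitalized patients as non-hospitalized.
#'
#' Prior hospitalizations are counted over `prior_window` regardless of
#' outcome. Discharge records with `discharge_date < admission_date`
#' are rejected with a warning.
#'
#' @param registry registry table (`patient_id`, `sex`, `birth_date`,
#'   `death_date` with `NA` for alive)
#' @param discharges discharge table
#' @param statuses [summarize_counts()] output; patients absent from it
#'   (no counted drugs under a restrictive definition) enter with a
#'   zero count in the reference bin
#' @param observation_year calendar year of exposure assessment; age is
#'   computed at 31 December of it
#' @param outcome_window length-2 `Date` vector, inclusive; default
#'   1 Jan - 30 Jun of the following year
#' @param prior_window length-2 `Date` vector for the prior-admission
#'   count; default the four years ending with the observation year
#' @return `data.table` with one row per registry patient:
#'   `patient_id`, `poly5`, `poly10`, `class_bin`, `summary_count`,
#'   `sex`, `age_years`, `prior_hospitalizations`, `outcome`,
#'   `excluded`, `exclusion_reason`
#' @export
assemble_cohort <- function(registry, discharges, statuses,
                            observation_year = 2017L,
                            outcome_window = NULL,
                            prior_window = NULL) {
  reg <- validate_registry(registry)
  dc <- validate_discharges(discharges)
  if (is.null(outcome_window)) {
    outcome_window <- c(year_start(observation_year + 1L),
                        as.Date(sprintf("%d-06-30", observation_year + 1L)))
  }
  if (is.null(prior_window)) {
    prior_window <- c(year_start(observation_year - 3L),
                      as.Date(sprintf("%d-12-31", observation_year)))
  }
  second_half <- c(as.Date(sprintf("%d-07-01", observation_year + 1L)),
                   as.Date(sprintf("%d-12-31", observation_year + 1L)))
  end_outcome_year <- as.Date(sprintf("%d-12-31", observation_year + 1L))

  out <- reg[, .(patient_id, sex, birth_date, death_date)]
  out[, age_years := age_at(birth_date,
                            as.Date(sprintf("%d-12-31", observation_year)))]

  flag_any <- function(lo, hi) {
    ids <- unique(dc[admission_date >= lo & admission_date <= hi, patient_id])
    out$patient_id %in% ids
  }
  out[, outcome := flag_any(outcome_window[1], outcome_window[2])]
  second_half_any <- flag_any(second_half[1], second_half[2])

  prior <- dc[admission_date >= prior_window[1] &
                admission_date <= prior_window[2],
              .(prior_hospitalizations = .N), by = patient_id]
  out <- prior[out, on = "patient_id"]
  out[is.na(prior_hospitalizations), prior_hospitalizations := 0L]

  out[, excluded := FALSE]
  out[, exclusion_reason := NA_character_]
  out[!outcome & second_half_any,
      `:=`(excluded = TRUE,
           exclusion_reason = "second_half_only_hospitalization")]
  out[!is.na(death_date) & death_date <= end_outcome_year,
      `:=`(excluded = TRUE, exclusion_reason = "died_before_end_period")]

  st <- as.data.table(statuses)
  out[, `:=`(summary_count = 0, poly5 = FALSE, poly10 = FALSE)]
  out[st, on = "patient_id",
      `:=`(summary_count = i.summary_count, poly5 = i.poly5,
           poly10 = i.poly10)]
  out[, class_bin := bin_count(summary_count)]
  out[st, on = "patient_id", class_bin := i.class_bin]
  setcolorder(out, c("patient_id", "poly5", "poly10", "class_bin",
                     "summary_count", "sex", "age_years",
                     "prior_hospitalizations", "outcome", "excluded",
                     "exclusion_reason"))
  setorder(out, patient_id)
  out[]
}

#' Odds ratios for all-cause hospitalization
#'
#' Fits logistic regression of the hospitalization outcome on
#' polypharmacy exposure over the non-excluded cohort rows. The crude
#' model contains the exposure alone; the adjusted model adds sex, age
#' (continuous, years at 31 Dec of the observation year) and the
#' prior-hospitalization count (continuous). With
#' `exposure = "class_bin"` the 1-4 bin is the reference and one
#' indicator per higher bin is fit. Confidence intervals are Wald
#' intervals on the log-odds scale.
#'
#' @param cohort [assemble_cohort()] output
#' @param exposure `"poly5"` or `"class_bin"`
#' @param adjusted logical
#' @param conf_level confidence level (default 0.95)
#' @return `data.table` with one row per exposure contrast: `term`,
#'   `or`, `lcl`, `ucl`, `adjusted`, plus `converged`. A model failure
#'   yields `NA` estimates rather than an error.
#' @export
fit_association <- function(cohort, exposure = c("poly5", "class_bin"),
                            adjusted = FALSE, conf_level = 0.95) {
  exposure <- match.arg(exposure)
  dat <- as.data.table(cohort)[excluded == FALSE]
  dat <- dat[, .(outcome = as.integer(outcome),
                 poly5 = as.logical(poly5),
                 class_bin = factor(class_bin, levels = POLY_BIN_LEVELS),
                 sex = factor(sex, levels = c("F", "M")),
                 age_years, prior_hospitalizations)]
  rhs <- exposure
  if (adjusted) {
    rhs <- paste(rhs, "+ sex + age_years + prior_hospitalizations")
  }
  fml <- stats::as.formula(paste("outcome ~", rhs))
  fit <- tryCatch(
    stats::glm(fml, family = binomial(), data = dat,
               control = glm.control(epsilon = 1e-10, maxit = 50)),
    error = function(e) NULL,
    warning = function(w) {
      ## refit, keeping the result but flagging non-convergence via
      ## the `converged` slot glm itself maintains
      suppressWarnings(stats::glm(fml, family = binomial(), data = dat,
                                  control = glm.control(epsilon = 1e-10,
                                                        maxit = 50)))
    })
  terms_wanted <- if (exposure == "poly5") "poly5TRUE" else {
    paste0("class_bin", POLY_BIN_LEVELS[-1])
  }
  if (is.null(fit)) {
    return(data.table(term = terms_wanted, or = NA_real_, lcl = NA_real_,
                      ucl = NA_real_, adjusted = adjusted,
                      converged = FALSE))
  }
  est <- coef(fit)[terms_wanted]
  se <- sqrt(diag(vcov(fit))[terms_wanted])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.table(term = terms_wanted,
             or = exp(unname(est)),
             lcl = exp(unname(est - z * se)),
             ucl = exp(unname(est + z * se)),
             adjusted = adjusted,
             converged = isTRUE(fit$converged))
}

## ---- validation ------------------------------------------------------

validate_registry <- function(registry) {
  need <- c("patient_id", "sex", "birth_date")
  miss <- setdiff(need, names(registry))
  if (length(miss)) {
    stop("registry is missing column(s): ", paste(miss, collapse = ", "))
  }
  reg <- as.data.table(registry)
  reg <- copy(reg)
  if (!"death_date" %in% names(reg)) reg[, death_date := as.Date(NA)]
  for (col in c("birth_date", "death_date")) {
    if (!identical(class(reg[[col]]), "Date")) {
      v <- reg[[col]]
      if (is.character(v)) v[v == ""] <- NA
      set(reg, j = col, value = as.Date(v))
    }
  }
  if (!all(reg$sex %in% c("F", "M"))) stop("registry sex must be F or M")
  reg
}

validate_discharges <- function(discharges) {
  need <- c("patient_id", "admission_date", "discharge_date")
  miss <- setdiff(need, names(discharges))
  if (length(miss)) {
    stop("discharge table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  dc <- copy(as.data.table(discharges))
  for (col in c("admission_date", "discharge_date")) {
    if (!identical(class(dc[[col]]), "Date")) {
      set(dc, j = col, value = as.Date(dc[[col]]))
    }
  }
  bad <- dc$discharge_date < dc$admission_date
  if (any(bad)) {
    warning(sum(bad), " discharge record(s) with discharge before ",
            "admission rejected")
    dc <- dc[!bad]
  }
  dc
}
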