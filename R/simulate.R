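## Default therapeutic-class pools. Chronic classes refill
## near-periodically all year (interval ~ one package's DDD content);
## acute classes come from the ATC groups the Chronic ATC definition
## excludes (short-term treatments), as short isolated courses.
default_chronic_pool <- function() {
  data.table(
    atc = c("C10AA", "C09AA", "C07AB", "C08CA", "A02BC", "B01AC",
            "A10BA", "N03AX", "N05BA", "R03AK", "H03AA", "M04AA",
            "C03CA", "N06AB"),
    ddd_per_package = c(28, 28, 28, 28, 14, 30, 50, 30, 20, 30, 50,
                        30, 30, 28)
  )
}

default_acute_pool <- function() {
  data.table(
    atc = c("J01CR", "J01MA", "A01AB", "A06AD", "J02AC", "D01AC",
            "V03AB", "P03AX", "J05AB", "J06BA", "J07BB")
  )
}

## excluded-group filler so a patient with no assigned classes still
## has one dispensing (the cohort requires >= 1 refill in the year)
FILLER_ATC <- "V07AB"
FILLER_DDDS <- 10

#' Configuration of the synthetic claims generator
#'
#' Defines a simulated assisted population with known chronic-treatment
#' structure and a known polypharmacy-hospitalization odds ratio. The
#' defaults emulate an adult (>= 40) pharmacy-claims cohort: each
#' patient carries a Poisson number of chronic ATC fourth-level
#' classes refilled near-periodically with timing jitter (creating
#' both gaps and same-class overlaps), short acute courses drawn from
#' short-term-treatment ATC groups, and an all-cause hospitalization
#' outcome generated from a logistic model in which carrying >= 5
#' chronic classes multiplies the odds by `true_outcome_or`.
#'
#' @param n_patients number of patients
#' @param observation_year exposure year (default 2017)
#' @param age_range inclusive integer age range at 31 Dec of the
#'   observation year (minimum 40)
#' @param chronic_class_pool `data.frame` with `atc` (5-char class) and
#'   `ddd_per_package`; the refill interval of a class equals its
#'   package DDD content
#' @param acute_class_pool `data.frame` with `atc`; must be disjoint
#'   from the chronic pool
#' @param mean_chronic_classes_per_patient Poisson mean of chronic
#'   classes per patient (truncated at the pool size)
#' @param refill_jitter_days refill timing noise: each inter-fill gap
#'   is the interval plus a uniform integer in `[-jitter, +jitter]`
#' @param acute_courses_mean Poisson mean of acute courses per patient
#' @param true_outcome_or odds ratio linking the >= 5-chronic-class
#'   exposure to hospitalization in the first half of the following
#'   year
#' @param baseline_outcome_prob outcome probability of an unexposed
#'   patient at the covariate reference (age 65, female, no prior
#'   admissions)
#' @param age_log_or,male_log_or small covariate effects on the
#'   log-odds scale (per decade of age over 65; male vs female)
#' @param prior_log_or log-odds increment per prior hospitalization
#'   (default 0: prior admissions are then not a confounder and the
#'   crude odds ratio recovers `true_outcome_or`)
#' @param prior_hosp_mean Poisson mean of 2014-2017 admissions for
#'   unexposed patients
#' @param prior_hosp_rr multiplier of that mean for exposed patients
#' @param stay_mean mean hospital stay length in days
#' @param long_stay_extra_days additional mean stay for exposed
#'   patients (sicker polypharmacy patients stay longer)
#' @param second_half_admission_prob probability of an admission in the
#'   second half of the outcome year unrelated to the modelled outcome
#' @param death_prob probability of death during the outcome year
#' @param seed integer seed; fully determines the output. Per-patient
#'   substreams are derived from it, so enlarging `n_patients` leaves
#'   earlier patients' records unchanged.
#' @return a `sim_config` list
#' @export
sim_config <- function(n_patients = 1000L,
                       observation_year = 2017L,
                       age_range = c(40L, 95L),
                       chronic_class_pool = default_chronic_pool(),
                       acute_class_pool = default_acute_pool(),
                       mean_chronic_classes_per_patient = 4,
                       refill_jitter_days = 5L,
                       acute_courses_mean = 1.5,
                       true_outcome_or = 2.5,
                       baseline_outcome_prob = 0.05,
                       age_log_or = 0.05,
                       male_log_or = 0.05,
                       prior_log_or = 0,
                       prior_hosp_mean = 0.3,
                       prior_hosp_rr = 1,
                       stay_mean = 6,
                       long_stay_extra_days = 3,
                       second_half_admission_prob = 0.03,
                       death_prob = 0.01,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              observation_year = as.integer(observation_year),
              age_range = as.integer(age_range),
              chronic_class_pool = as.data.table(chronic_class_pool),
              acute_class_pool = as.data.table(acute_class_pool),
              mean_chronic_classes_per_patient =
                mean_chronic_classes_per_patient,
              refill_jitter_days = as.integer(refill_jitter_days),
              acute_courses_mean = acute_courses_mean,
              true_outcome_or = true_outcome_or,
              baseline_outcome_prob = baseline_outcome_prob,
              age_log_or = age_log_or, male_log_or = male_log_or,
              prior_log_or = prior_log_or,
              prior_hosp_mean = prior_hosp_mean,
              prior_hosp_rr = prior_hosp_rr,
              stay_mean = stay_mean,
              long_stay_extra_days = long_stay_extra_days,
              second_half_admission_prob = second_half_admission_prob,
              death_prob = death_prob,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  err <- function(field, msg) {
    stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  if (cfg$n_patients < 1L) err("n_patients", "must be >= 1")
  if (length(cfg$age_range) != 2L || cfg$age_range[1] < 40L ||
      cfg$age_range[2] < cfg$age_range[1]) {
    err("age_range", "must be an increasing pair with minimum >= 40")
  }
  for (p in c("baseline_outcome_prob", "second_half_admission_prob",
              "death_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) err(p, "must be in [0, 1]")
  }
  if (cfg$true_outcome_or <= 0) err("true_outcome_or", "must be positive")
  if (cfg$mean_chronic_classes_per_patient < 0) {
    err("mean_chronic_classes_per_patient", "must be nonnegative")
  }
  if (cfg$refill_jitter_days < 0) {
    err("refill_jitter_days", "must be nonnegative")
  }
  if (nrow(cfg$chronic_class_pool)) {
    if (!all(c("atc", "ddd_per_package") %in%
             names(cfg$chronic_class_pool))) {
      err("chronic_class_pool", "needs columns atc, ddd_per_package")
    }
    if (any(cfg$chronic_class_pool$ddd_per_package <= 0)) {
      err("chronic_class_pool", "ddd_per_package must be positive")
    }
  }
  both <- intersect(substr(cfg$chronic_class_pool$atc, 1, 5),
                    substr(cfg$acute_class_pool$atc, 1, 5))
  if (length(both)) {
    err("acute_class_pool",
        paste("overlaps chronic pool at:", paste(both, collapse = ", ")))
  }
  invisible(cfg)
}

## deterministic per-patient substream seed (31-bit)
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Simulate one patient's refill stream
#'
#' Chronic classes are anchored at a uniform start day (possibly late
#' in the prior year) and refilled at their package-DDD interval plus
#' uniform jitter, producing both coverage gaps and refills dispensed
#' before the previous coverage ends; acute classes appear as single
#' short courses (5-14 DDDs) uniformly over the year.
#'
#' @param patient_id patient identifier
#' @param chronic_classes `data.table` rows of the chronic pool
#'   assigned to this patient
#' @param n_acute number of acute courses
#' @param config a [sim_config()]
#' @return list of refill-table columns (`patient_id`, `dispense_day`
#'   as day offsets, `atc_code`, `n_packages`, `ddd_per_package`)
#' @export
generate_refill_stream <- function(patient_id, chronic_classes, n_acute,
                                   config) {
  yl <- year_length(config$observation_year)
  day <- integer(0); atc <- character(0); ddd <- numeric(0)
  if (nrow(chronic_classes)) {
    for (k in seq_len(nrow(chronic_classes))) {
      interval <- chronic_classes$ddd_per_package[k]
      anchor <- as.integer(floor(runif(1, -45, yl - 30)))
      d <- anchor
      ds <- integer(0)
      while (d < yl) {
        ds <- c(ds, d)
        j <- if (config$refill_jitter_days > 0) {
          sample(seq(-config$refill_jitter_days,
                     config$refill_jitter_days), 1L)
        } else 0L
        d <- d + max(1L, as.integer(round(interval)) + j)
      }
      day <- c(day, ds)
      atc <- c(atc, rep(chronic_classes$atc[k], length(ds)))
      ddd <- c(ddd, rep(interval, length(ds)))
    }
  }
  if (n_acute > 0L && nrow(config$acute_class_pool)) {
    a_atc <- sample(config$acute_class_pool$atc, n_acute, replace = TRUE)
    a_day <- as.integer(floor(runif(n_acute, 0, yl)))
    a_ddd <- as.integer(floor(runif(n_acute, 5, 15)))
    day <- c(day, a_day); atc <- c(atc, a_atc); ddd <- c(ddd, a_ddd)
  }
  if (!length(day)) {
    day <- as.integer(floor(runif(1, 0, yl)))
    atc <- FILLER_ATC
    ddd <- FILLER_DDDS
  }
  list(patient_id = rep(patient_id, length(day)),
       dispense_day = as.integer(day),
       atc_code = atc,
       n_packages = rep(1L, length(day)),
       ddd_per_package = ddd)
}

#' Generate a synthetic assisted population
#'
#' Produces the three administrative tables a claims-based polypharmacy
#' analysis consumes — assisted-residents registry, pharmacy refills,
#' hospital discharges — together with a ground-truth table recording
#' each patient's assigned chronic-class count, exposure flag
#' (>= 5 chronic classes) and generated outcome, for validation of the
#' downstream pipeline.
#'
#' @param config a [sim_config()]
#' @return list with `data.table`s `registry` (`patient_id`, `sex`,
#'   `birth_date`, `death_date`), `refills` (`patient_id`,
#'   `dispense_date`, `atc_code`, `n_packages`, `ddd_per_package`),
#'   `discharges` (`patient_id`, `admission_date`, `discharge_date`),
#'   `truth` (`patient_id`, `n_chronic_classes`, `exposed`, `outcome`,
#'   `prior_hospitalizations`), and the `config`
#' @examples
#' pop <- simulate_claims(sim_config(n_patients = 50, seed = 7))
#' names(pop)
#' @export
simulate_claims <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  yr <- config$observation_year
  yl <- year_length(yr)
  n <- config$n_patients
  npool <- nrow(config$chronic_class_pool)

  ids <- sprintf("P%06d", seq_len(n))
  reg_sex <- character(n); reg_age <- integer(n)
  reg_birth_off <- integer(n); reg_death <- rep(NA_integer_, n)
  truth_nchronic <- integer(n); truth_outcome <- logical(n)
  truth_prior <- integer(n)
  refill_parts <- vector("list", n)
  disc_parts <- vector("list", n)

  ref_end <- as.Date(sprintf("%d-12-31", yr))
  h1_start <- day_offset(year_start(yr + 1L), yr)
  h1_len <- as.integer(as.Date(sprintf("%d-06-30", yr + 1L)) -
                         year_start(yr + 1L)) + 1L
  h2_start <- day_offset(as.Date(sprintf("%d-07-01", yr + 1L)), yr)
  h2_len <- as.integer(as.Date(sprintf("%d-12-31", yr + 1L)) -
                         as.Date(sprintf("%d-07-01", yr + 1L))) + 1L
  prior_start <- day_offset(year_start(yr - 3L), yr)
  prior_len <- as.integer(ref_end - year_start(yr - 3L)) + 1L

  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    pid <- ids[i]

    age <- as.integer(floor(runif(1, config$age_range[1],
                                  config$age_range[2] + 1)))
    sex <- if (runif(1) < 0.55) "F" else "M"
    ## born on a random day of year (yr - age): completed age at 31 Dec
    ## of the observation year is then exactly `age`
    birth_off <- day_offset(year_start(yr - age), yr) +
      as.integer(floor(runif(1, 0, 365)))
    reg_sex[i] <- sex; reg_age[i] <- age; reg_birth_off[i] <- birth_off

    k <- min(npool, rpois(1, config$mean_chronic_classes_per_patient))
    chronic <- if (k > 0L) {
      config$chronic_class_pool[sample(npool, k), ]
    } else config$chronic_class_pool[0L, ]
    n_acute <- rpois(1, config$acute_courses_mean)
    refill_parts[[i]] <- generate_refill_stream(pid, chronic, n_acute,
                                                config)
    truth_nchronic[i] <- k
    exposed <- k >= 5L

    prior <- rpois(1, config$prior_hosp_mean *
                     if (exposed) config$prior_hosp_rr else 1)
    truth_prior[i] <- prior

    lp <- qlogis(config$baseline_outcome_prob) +
      log(config$true_outcome_or) * exposed +
      config$age_log_or * (age - 65) / 10 +
      config$male_log_or * (sex == "M") +
      config$prior_log_or * prior
    outcome <- runif(1) < plogis(lp)
    truth_outcome[i] <- outcome

    adm <- integer(0)
    if (prior > 0L) {
      adm <- c(adm, prior_start +
                 as.integer(floor(runif(prior, 0, prior_len))))
    }
    if (outcome) {
      adm <- c(adm, h1_start + as.integer(floor(runif(1, 0, h1_len))))
    }
    if (runif(1) < config$second_half_admission_prob) {
      adm <- c(adm, h2_start + as.integer(floor(runif(1, 0, h2_len))))
    }
    if (length(adm)) {
      stay <- 1L + rpois(length(adm),
                         config$stay_mean - 1 +
                           if (exposed) config$long_stay_extra_days else 0)
      disc_parts[[i]] <- list(patient_id = rep(pid, length(adm)),
                              admission_day = adm,
                              discharge_day = adm + stay)
    }
    if (runif(1) < config$death_prob) {
      reg_death[i] <- h1_start + as.integer(floor(runif(1, 0, 365)))
    }
  }

  origin <- year_start(yr)
  refills <- rbindlist(refill_parts)
  refills[, dispense_date := origin + dispense_day]
  refills[, dispense_day := NULL]
  setcolorder(refills, c("patient_id", "dispense_date", "atc_code",
                         "n_packages", "ddd_per_package"))

  disc_parts <- disc_parts[!vapply(disc_parts, is.null, logical(1))]
  discharges <- if (length(disc_parts)) {
    dd <- rbindlist(disc_parts)
    dd[, `:=`(admission_date = origin + admission_day,
              discharge_date = origin + discharge_day)]
    dd[, c("admission_day", "discharge_day") := NULL]
    dd
  } else {
    data.table(patient_id = character(0),
               admission_date = as.Date(character(0)),
               discharge_date = as.Date(character(0)))
  }

  registry <- data.table(
    patient_id = ids, sex = reg_sex,
    birth_date = origin + reg_birth_off,
    death_date = origin + reg_death  # NA offsets stay NA
  )
  truth <- data.table(patient_id = ids,
                      n_chronic_classes = truth_nchronic,
                      exposed = truth_nchronic >= 5L,
                      outcome = truth_outcome,
                      prior_hospitalizations = truth_prior)
  list(registry = registry, refills = refills, discharges = discharges,
       truth = truth, config = config)
}
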