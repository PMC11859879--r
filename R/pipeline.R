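#' Configure an end-to-end polypharmacy analysis
#'
#' A run either reads the three administrative tables from
#' `registry_path` / `refills_path` / `discharges_path` or simulates
#' them from a [sim_config()] given as `simulate`.
#'
#' @param simulate a [sim_config()], or `NULL` to read files
#' @param registry_path,refills_path,discharges_path input table paths
#'   (ignored when `simulate` is given)
#' @param sep input delimiter
#' @param observation_year exposure year
#' @param definitions subset of `c("ALL_ATC", "CHRONIC_ATC",
#'   "DDD_GE_60")`
#' @param granularities subset of `c("ANNUAL", "QUARTER", "MONTH")`
#' @param aggregation `"MAX"`, `"MEAN"` or `"COVERED_FRACTION"`
#' @param covered_fraction only for `COVERED_FRACTION` aggregation
#' @param rounding days-supply rounding mode (see [days_supply()])
#' @param ddd_attribution annual DDD-total attribution (see
#'   [annual_ddd_totals()])
#' @param outcome_end last day (`Date` or string) of the outcome
#'   window; default 30 June of the year after the observation year
#' @param output_dir directory for the report files
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(simulate = NULL,
                            registry_path = NULL, refills_path = NULL,
                            discharges_path = NULL, sep = ",",
                            observation_year = 2017L,
                            definitions = c("ALL_ATC", "CHRONIC_ATC",
                                            "DDD_GE_60"),
                            granularities = c("ANNUAL", "QUARTER",
                                              "MONTH"),
                            aggregation = "MAX",
                            covered_fraction = NULL,
                            rounding = "round",
                            ddd_attribution = "covered",
                            outcome_end = NULL,
                            output_dir = NULL) {
  definitions <- match.arg(definitions, several.ok = TRUE)
  granularities <- match.arg(granularities, several.ok = TRUE)
  if (is.null(simulate) &&
      (is.null(registry_path) || is.null(refills_path) ||
       is.null(discharges_path))) {
    stop("either `simulate` or all three input paths must be given")
  }
  structure(list(simulate = simulate, registry_path = registry_path,
                 refills_path = refills_path,
                 discharges_path = discharges_path, sep = sep,
                 observation_year = as.integer(observation_year),
                 definitions = definitions,
                 granularities = granularities,
                 aggregation = aggregation,
                 covered_fraction = covered_fraction,
                 rounding = rounding, ddd_attribution = ddd_attribution,
                 outcome_end = outcome_end, output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; a `simulate`
#' block mirrors [sim_config()].
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate <- do.call(sim_config, y$simulate)
  }
  do.call(pipeline_config, y)
}

#' Run the full polypharmacy analysis
#'
#' Loads (or simulates) the claims tables, builds the supply diary,
#' applies every requested definition over every requested window
#' granularity, and produces:
#' * `prevalence_by_class` — patient counts and percentages per
#'   definition x granularity x polypharmacy class bin;
#' * `poly_prevalence` — the >= 5 and >= 10 prevalences;
#' * `cohort_characteristics` — per definition x granularity, the
#'   on-polypharmacy subgroup's size, percent female, mean (SD) age,
#'   mean (SD) drug count, percent with a prior hospitalization, and
#'   percent hospitalized in the outcome window;
#' * `association_poly5` — crude and adjusted odds ratios of
#'   hospitalization for the >= 5-drug exposure;
#' * `association_by_class` — adjusted per-class odds ratios (1-4 as
#'   reference).
#'
#' All tables are computed first and written together at the end (no
#' partial output directories); given the same configuration the run
#' is fully deterministic.
#'
#' @param config a [pipeline_config()]
#' @param quiet suppress per-stage log messages
#' @return invisibly, a named list of the report `data.table`s plus
#'   `log` (character vector of stage messages)
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (!quiet) message(msg)
    invisible(NULL)
  }
  year <- config$observation_year

  if (!is.null(config$simulate)) {
    pop <- simulate_claims(config$simulate)
    registry <- pop$registry; refills <- pop$refills
    discharges <- pop$discharges
    say("simulated %d patients (seed %d)", nrow(registry),
        config$simulate$seed)
  } else {
    registry <- read_registry(config$registry_path, config$sep)
    refills <- read_refills(config$refills_path, config$sep)
    discharges <- read_discharges(config$discharges_path, config$sep)
    say("read %d registry rows, %d refills, %d discharges",
        nrow(registry), nrow(refills), nrow(discharges))
  }

  diary <- build_supply_diary(refills, year, config$rounding)
  ddd_totals <- annual_ddd_totals(refills, diary, year,
                                  config$ddd_attribution)
  diary_year_only <- clip_diary(diary)
  patients <- sort(unique(diary_year_only$patient_id))
  say("supply diary: %d segments, %d patients with coverage in %d",
      nrow(diary_year_only), length(patients), year)

  scheme_for <- function(granularity) {
    window_scheme(granularity, config$aggregation,
                  config$covered_fraction)
  }
  outcome_window <- if (is.null(config$outcome_end)) NULL else {
    c(year_start(year + 1L), as.Date(config$outcome_end))
  }

  prev_rows <- list(); poly_rows <- list(); char_rows <- list()
  assoc_rows <- list(); class_rows <- list()
  for (def_name in config$definitions) {
    spec <- definition_spec(def_name)
    def_diary <- apply_definition(diary_year_only, spec, ddd_totals)
    for (gran in config$granularities) {
      counts <- count_per_window(def_diary, gran, patients)
      statuses <- summarize_counts(counts, scheme_for(gran))
      key <- list(definition = def_name, granularity = gran)

      pbc <- prevalence_by_class(statuses)
      prev_rows[[length(prev_rows) + 1L]] <-
        cbind(as.data.table(key), pbc)
      p5 <- prevalence(statuses, "poly5")
      p10 <- prevalence(statuses, "poly10")
      poly_rows[[length(poly_rows) + 1L]] <- data.table(
        definition = def_name, granularity = gran,
        n_poly5 = p5$count, pct_poly5 = p5$percent,
        n_poly10 = p10$count, pct_poly10 = p10$percent,
        cohort_n = p5$n)

      cohort <- assemble_cohort(registry, discharges, statuses, year,
                                outcome_window)
      say("%s/%s: %d poly5, %d excluded (%s)", def_name, gran,
          p5$count, sum(cohort$excluded),
          paste(names(table(cohort$exclusion_reason)), collapse = "/"))

      sub <- cohort[poly5 == TRUE]
      char_rows[[length(char_rows) + 1L]] <- data.table(
        definition = def_name, granularity = gran, n = nrow(sub),
        pct_female = prevalence_pct(sum(sub$sex == "F"),
                                    max(1L, nrow(sub))),
        age_mean = round_half_up(mean(sub$age_years), 1L),
        age_sd = round_half_up(stats::sd(sub$age_years), 1L),
        drugs_mean = round_half_up(mean(sub$summary_count), 1L),
        drugs_sd = round_half_up(stats::sd(sub$summary_count), 1L),
        pct_prior_hosp = prevalence_pct(
          sum(sub$prior_hospitalizations > 0), max(1L, nrow(sub))),
        pct_outcome = prevalence_pct(
          sum(sub$outcome[!sub$excluded]),
          max(1L, sum(!sub$excluded))))

      crude <- fit_association(cohort, "poly5", adjusted = FALSE)
      adj <- fit_association(cohort, "poly5", adjusted = TRUE)
      assoc_rows[[length(assoc_rows) + 1L]] <-
        cbind(as.data.table(key), rbind(crude, adj))
      cls <- fit_association(cohort, "class_bin", adjusted = TRUE)
      class_rows[[length(class_rows) + 1L]] <-
        cbind(as.data.table(key), cls)
    }
  }

  reports <- list(prevalence_by_class = rbindlist(prev_rows),
                  poly_prevalence = rbindlist(poly_rows),
                  cohort_characteristics = rbindlist(char_rows),
                  association_poly5 = rbindlist(assoc_rows),
                  association_by_class = rbindlist(class_rows),
                  log = log)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(reports), "log")) {
      fwrite(reports[[nm]], file.path(config$output_dir,
                                      paste0(nm, ".csv")))
    }
    yamlify <- function(x) {
      if (is.data.frame(x)) lapply(as.list(x), yamlify)
      else if (is.list(x)) lapply(x, yamlify)
      else if (inherits(x, "Date")) as.character(x)
      else x
    }
    resolved <- c(list(polyrx_version =
                         as.character(packageVersion("polyrx"))),
                  yamlify(unclass(config)))
    yaml::write_yaml(resolved,
                     file.path(config$output_dir, "config_resolved.yaml"))
    writeLines(log, file.path(config$output_dir, "run_log.txt"))
  }
  invisible(reports)
}
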