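#' Read the three administrative tables
#'
#' Readers for the delimited-text schemas of the assisted-residents
#' registry, the pharmacy refill archive and the hospital discharge
#' archive. Dates must be ISO-8601 (`YYYY-MM-DD`); an empty
#' `death_date` means alive. Schema violations are reported with the
#' offending rows.
#'
#' @param path file path
#' @param sep field delimiter (default comma)
#' @return a validated `data.table`
#' @name claims_io
NULL

#' @rdname claims_io
#' @export
read_refills <- function(path, sep = ",") {
  rf <- fread(path, sep = sep, colClasses = list(character = "patient_id"))
  check_dates(rf, "dispense_date", path)
  validate_refills(rf)
}

#' @rdname claims_io
#' @export
read_registry <- function(path, sep = ",") {
  reg <- fread(path, sep = sep,
               colClasses = list(character = c("patient_id")),
               na.strings = "")
  check_dates(reg, "birth_date", path)
  validate_registry(reg)
}

#' @rdname claims_io
#' @export
read_discharges <- function(path, sep = ",") {
  dc <- fread(path, sep = sep, colClasses = list(character = "patient_id"))
  check_dates(dc, c("admission_date", "discharge_date"), path)
  validate_discharges(dc)
}

check_dates <- function(dt, cols, path) {
  for (col in cols) {
    if (!col %in% names(dt)) {
      stop(path, ": missing column `", col, "`")
    }
    v <- dt[[col]]
    if (inherits(v, "Date")) next
    parsed <- as.Date(as.character(v), format = "%Y-%m-%d")
    bad <- which(!is.na(v) & v != "" & is.na(parsed))
    if (length(bad)) {
      stop(path, ": unparseable ISO-8601 dates in `", col, "` at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  invisible(dt)
}

#' Write simulated claims tables to delimited text
#'
#' @param population a [simulate_claims()] result
#' @param dir output directory (created if absent)
#' @param sep field delimiter
#' @return invisibly, the paths written (registry, refills, discharges)
#' @export
write_claims_tables <- function(population, dir, sep = ",") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("registry.csv", "refills.csv",
                            "discharges.csv"))
  fwrite(population$registry, paths[1], sep = sep, dateTimeAs = "ISO")
  fwrite(population$refills, paths[2], sep = sep, dateTimeAs = "ISO")
  fwrite(population$discharges, paths[3], sep = sep, dateTimeAs = "ISO")
  invisible(stats::setNames(paths, c("registry", "refills", "discharges")))
}
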