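## Brute-force day-stack oracle: supply is banked on the dispensing
## day and one DDD-day is consumed per covered day, independently per
## ATC fourth-level class. Returns the set of covered day offsets.
oracle_covered_set <- function(dispense_days, supplies) {
  stopifnot(length(dispense_days) == length(supplies))
  base <- min(dispense_days)
  horizon <- max(dispense_days) - base + sum(supplies) + 2L
  add <- numeric(horizon)
  for (i in seq_along(dispense_days)) {
    j <- dispense_days[i] - base + 1L
    add[j] <- add[j] + supplies[i]
  }
  bank <- 0
  covered <- logical(horizon)
  for (d in seq_len(horizon)) {
    bank <- bank + add[d]
    if (bank > 0) {
      covered[d] <- TRUE
      bank <- bank - 1
    }
  }
  which(covered) + base - 1L
}

## covered-day set of one class in a diary (half-open segments)
diary_covered_set <- function(diary, cls) {
  seg <- diary[diary$atc4 == cls, ]
  if (nrow(seg) == 0L) return(integer(0))
  sort(unlist(mapply(seq, seg$start_day, seg$end_day - 1L,
                     SIMPLIFY = FALSE)))
}

## random one-patient refill table over late 2016 through 2017
random_refills <- function(n_fills, patient_id = "px",
                           classes = c("C10AA", "A02BC", "N05BA")) {
  data.frame(
    patient_id = patient_id,
    dispense_date = as.Date("2017-01-01") +
      sample(-60:330, n_fills, replace = TRUE),
    atc_code = paste0(sample(classes, n_fills, replace = TRUE), "05"),
    n_packages = sample(1:3, n_fills, replace = TRUE),
    ddd_per_package = sample(c(7, 10, 14, 16.5, 28, 30), n_fills,
                             replace = TRUE),
    record_id = seq_len(n_fills)
  )
}

## minimal refill row constructor for hand-built cases
refill_row <- function(patient_id, date, atc, n_pkg = 1, ddd = 30) {
  data.frame(patient_id = patient_id, dispense_date = as.Date(date),
             atc_code = atc, n_packages = n_pkg,
             ddd_per_package = ddd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
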