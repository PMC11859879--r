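Package: polyrx
Title: Operational Polypharmacy Definitions from Pharmacy Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs drug-exposure histories from pharmacy refill
    claims using defined-daily-dose (DDD) days of supply, chaining
    same-class refills with a shift-on-overlap rule into per-patient
    supply diaries. Implements three operational definitions of
    polypharmacy (all ATC fourth-level classes; chronic classes after
    excluding short-term-treatment ATC groups; classes with cumulative
    annual DDDs of at least 60) evaluated over annual, quarterly and
    monthly windows with maximum, mean and covered-fraction
    aggregation, and estimates crude and adjusted odds ratios for
    all-cause hospitalization. Includes a synthetic claims generator
    with known chronic-treatment structure and a known
    exposure-outcome odds ratio for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
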