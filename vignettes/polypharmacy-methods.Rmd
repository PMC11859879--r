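---
title: "Measuring polypharmacy from pharmacy claims: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring polypharmacy from pharmacy claims: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrx)
library(data.table)
```

## The measurement problem

Administrative pharmacy-claims archives record *dispensings* — a date,
an ATC code, a number of packages — not days of actual drug use.
Polypharmacy ("concurrent use of five or more medications", with
hyper-polypharmacy at ten or more) therefore has to be
*operationalized*: which drugs count, over which time window, and how
dispensings are converted into exposure time all change the prevalence
estimate and, potentially, the association with clinical outcomes such
as hospitalization. `polyrx` implements one coherent family of such
operational definitions end to end, so the consequences of each choice
can be examined on data with known ground truth.

## From dispensings to a supply diary

**Days of supply.** One WHO defined daily dose (DDD) is taken to cover
one day of therapy, so a dispensing of $n$ packages containing $q$
DDDs each covers $\mathrm{round}(n\,q)$ days. Rounding is half-up with
a floor of one day (a dispensing always covers at least its own day);
`floor` and `ceil` are available as configuration options because
claims DDD totals are frequently fractional and no convention is
universal. The choice only matters for classes dispensed in fractional
DDD multiples and never changes a count by more than one day per fill.

**Class interchangeability.** All drugs sharing an ATC fourth-level
code (the 5-character chemical subgroup, e.g. `C10AA`) are treated as
interchangeable: a switch between two statins continues one exposure
episode rather than starting a second one.

**The shift-on-overlap rule.** When a refill of a class is dispensed
before the previous supply of that class has run out, the patient is
assumed to finish the supply in hand first: the new fill's whole
coverage period starts the day after the previous coverage ends.
Within a class, supply is therefore *banked*, never double-counted and
never lost. Formally, processing fills in dispensing order (ties
broken by a stable record ordinal), fill $i$ covers
$[\max(d_i, e_{i-1}),\ \max(d_i, e_{i-1}) + s_i)$ where $d_i$ is its
dispensing day, $s_i$ its days of supply and $e_{i-1}$ the running end
of coverage. Two invariants follow and are asserted exactly in the
test suite: segments within a class never overlap, and total covered
days equal total days of supply. The interval construction is also
verified against an independent day-by-day simulation that banks
supply on the dispensing day and consumes one DDD-day per day.

Dispensings from the year before the observation year join the
chaining, so late prior-year supply shifted forward can cover days of
the observation year; the diary is then clipped to the year. Coverage
shifted past 31 December of the observation year is discarded by the
clipping — attributing it to the following year would change no
within-year count but would complicate the conservation invariant, so
truncation was chosen and is stated here explicitly. Stockpiling is
unbounded by default (no cap on how far supply may be shifted); a
`max_shift_days` option drops refills that would be displaced further
than the cap, for users who consider long displacement implausible.

## Three operational definitions

* **All ATC** — every dispensed ATC fourth-level class counts.
* **Chronic ATC** — classes in ATC groups usually dispensed for
  short-term treatment are excluded: the level-2 groups A01
  (stomatologicals), A06 (laxatives), J01/J02/J05 (systemic
  antibacterials, antimycotics, antivirals), J06/J07 (immune sera,
  vaccines), P03 (ectoparasiticides) and the level-1 groups D
  (dermatologicals) and V (various). Exclusion operates on whole
  fourth-level classes; since the prefixes sit at levels 1–2 this is
  identical to dropping individual prescriptions.
* **DDD ≥ 60** — only classes with cumulative annual DDDs of at least
  60 count, an implicit chronicity criterion.

For the DDD ≥ 60 totals, dispensed DDD content is attributed to the
observation year when the fill contributes at least one covered day to
it, consistent with the cohort-entry logic that admits prior-year
fills whose shifted coverage reaches the year. An alternative
(`attribution = "dispensed"`: sum over fills dispensed within the
year) is provided, since either reading is defensible; the two differ
only for fills near the year boundary.

## Windows, aggregation, and prevalence

Counts of distinct covered classes are computed per calendar window —
the year, the four calendar quarters, or the twelve calendar months —
with a class counting in a window if it has at least one covered day
in it. Monthly and quarterly measures are aggregated to a patient
summary by the **maximum** over windows (the primary rule: a patient
is "on polypharmacy" if any month/quarter reaches five classes), by
the **unrounded mean**, or by a **covered-fraction** rule that demands
at least 50%, 80% or 100% of the windows reach the threshold (6, 10 or
12 months). The mean is binned by the same cutpoints as integer counts
without rounding, because any rounding convention would silently move
borderline patients across the 5-drug threshold. Patients with zero
counted classes under a restrictive definition fall in the reference
bin (1–4); the cohort guarantees at least one dispensed drug overall,
not per definition.

Three orderings are structural and tested as invariants: restrictive
definitions never increase a count; monthly maxima never exceed
quarterly maxima, which never exceed the annual count; the mean never
exceeds the maximum, and covered-fraction prevalence is non-increasing
in the required fraction. Reported percentages are half-up rounded to
two decimals, matching how prevalence tables are conventionally
printed; the test suite confirms this arithmetic reproduces, to the
printed precision, every class-bin percentage of a published 431,620-
patient reference tabulation from its printed counts.

## The hospitalization cohort and models

The outcome is any all-cause admission in the first half of the year
after the observation year. The published design this follows contains
an internal inconsistency about the window's end date (1 June versus
"January to June"); since its exclusion rule is phrased around the
*halves* of the outcome year, the default here is 30 June, and the end
date is configurable. Two exclusions protect the outcome
classification: patients who die before the end of the outcome year,
and patients whose only outcome-year admission falls in its second
half (who would otherwise be misread as non-hospitalized). Prior
hospitalizations are counted over the four years ending with the
observation year, regardless of outcome.

Crude logistic models regress the outcome on the ≥ 5-drug flag (or on
class-bin indicators with 1–4 as reference); adjusted models add sex,
age at 31 December of the observation year, and the
prior-hospitalization count. Age and the prior count enter as
continuous covariates — the source design does not state a coding, and
continuous entry matches how the simulator generates the outcome, so
adjusted recovery of the simulated effect is exactly testable;
categorical alternatives can be fit by the user on the returned cohort
table. Confidence intervals are Wald intervals on the log-odds scale
(the method is not named in the source design; Wald is the convention
large administrative cohorts report). Non-convergence or separation
yields `NA` estimates with a `converged` flag rather than an error.

## What the synthetic cohort emulates — and what it does not

`simulate_claims()` generates the three administrative tables with
known truth. Defaults were fixed once, to resemble an adult
general-practice claims cohort:

* ages uniform 40–95, 55% female;
* a Poisson(4) number of chronic classes per patient from a 14-class
  pool (so roughly 37% of patients carry ≥ 5 chronic classes,
  comparable to annual polypharmacy prevalence in adult European
  claims cohorts), refilled at the package-DDD interval (14–50 days)
  with ±5 days of uniform timing jitter — producing both coverage gaps
  and early refills that exercise the shift rule;
* a Poisson(1.5) number of short acute courses (5–14 DDDs) drawn from
  the short-term-treatment ATC groups, so the Chronic ATC definition
  removes exactly the acute noise;
* outcome from a logistic model with odds ratio `true_outcome_or`
  (default 2.5) for the ≥ 5-chronic-class exposure plus small age and
  sex effects (0.05 log-odds per decade / for male sex); prior
  admissions Poisson(0.3), optionally enriched among the exposed and
  predictive of the outcome to create measurable confounding;
* hospital stays around 6 days, 3 days longer on average for exposed
  patients, so restricting to > 7-day stays enriches outcomes among
  the exposed — reproducing the direction of the severity sensitivity
  analysis.

Per-patient random substreams are derived deterministically from the
run seed, so enlarging the cohort never perturbs existing patients and
any patient's records can be regenerated in isolation.

The generator is deliberately structural, not market-realistic: it
does not model the Italian drug mix, seasonal prescribing, dosage
titration (DDD-based supply is exact in the simulation, whereas in
real claims DDDs misestimate individual posology), death during the
observation year, or correlation between chronic burden and age.
Passing tests therefore demonstrate that the *pipeline* measures what
it claims on data whose generating process is known — not that any
particular prevalence level generalizes to a real population.

## Validation problem sizes

The shipped checks use: 1,000 randomized patients (≤ 20 fills each)
for the interval-versus-day-stack oracle; 500–3,000 simulated patients
for invariants and directional sensitivity checks; and 50,000 patients
for odds-ratio recovery, where the claims-derived exposure agrees with
the generator's truth for > 99.9% of patients and crude and adjusted
estimates recover the simulated odds ratio within the Wald interval.

## Known limitations

Only DDD-based days of supply are implemented (no posology-adjusted
durations); switching versus duplication inside a class is not
adjudicated beyond interchangeability; hospitalizations are binary
all-cause (no cause-specific or time-to-event modelling); and the
covered-fraction rule is defined for the threshold flags, not for the
class bins, which under that rule report the maximum-based bin.
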