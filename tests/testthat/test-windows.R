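test_that("per-window class counts follow window membership", {
  full <- build_supply_diary(
    refill_row("p1", "2017-01-01", "C10AA05", ddd = 365))
  expect_equal(count_per_window(full, "MONTH")$n_classes, rep(1L, 12))
  expect_equal(count_per_window(full, "QUARTER")$n_classes, rep(1L, 4))
  expect_equal(count_per_window(full, "ANNUAL")$n_classes, 1L)

  short <- build_supply_diary(
    refill_row("p1", "2017-01-25", "C10AA05", ddd = 12))  # 25 Jan - 5 Feb
  expect_equal(count_per_window(short, "MONTH")$n_classes,
               c(1L, 1L, rep(0L, 10)))
  expect_equal(count_per_window(short, "QUARTER")$n_classes,
               c(1L, 0L, 0L, 0L))
})

test_that("per-window counts match a day-by-day distinct-class tally", {
  set.seed(7)
  for (rep in 1:15) {
    rf <- random_refills(sample(3:20, 1),
                         classes = c("C10AA", "A02BC", "N05BA", "C09AA"))
    d <- clip_diary(build_supply_diary(rf))
    wb <- window_bounds("MONTH", 2017)
    got <- count_per_window(d, "MONTH")
    for (w in 1:12) {
      days <- seq(wb$start_day[w], wb$end_day[w] - 1L)
      tally <- sum(vapply(unique(d$atc4), function(cls) {
        any(diary_covered_set(d, cls) %in% days)
      }, logical(1)))
      expect_identical(got$n_classes[got$window == w], as.integer(tally))
    }
  }
})

test_that("aggregation rules: maximum, unrounded mean, covered fraction", {
  cnt <- data.table::data.table(patient_id = "p1", window = 1:12,
                                n_classes = c(3L, 5L, 2L, rep(0L, 9)))
  mx <- summarize_counts(cnt, window_scheme("MONTH", "MAX"))
  expect_equal(mx$summary_count, 5)
  expect_true(mx$poly5); expect_false(mx$poly10)
  expect_equal(as.character(mx$class_bin), "5")

  me <- summarize_counts(cnt, window_scheme("MONTH", "MEAN"))
  expect_equal(me$summary_count, 10 / 12)
  expect_false(me$poly5)
  expect_equal(as.character(me$class_bin), "1-4")

  ## six months at >= 5 drugs: 50% of follow-up covered but not 80%
  cnt6 <- data.table::data.table(patient_id = "p1", window = 1:12,
                                 n_classes = c(rep(6L, 6), rep(2L, 6)))
  cf50 <- summarize_counts(cnt6,
                           window_scheme("MONTH", "COVERED_FRACTION", 0.5))
  cf80 <- summarize_counts(cnt6,
                           window_scheme("MONTH", "COVERED_FRACTION", 0.8))
  expect_true(cf50$poly5)
  expect_false(cf80$poly5)

  ## constant counts: mean equals max
  cntk <- data.table::data.table(patient_id = "p1", window = 1:4,
                                 n_classes = 7L)
  expect_equal(summarize_counts(cntk, window_scheme("QUARTER", "MEAN"))$summary_count,
               summarize_counts(cntk, window_scheme("QUARTER", "MAX"))$summary_count)

  expect_error(summarize_counts(cnt, window_scheme("QUARTER", "MAX")),
               "windows per patient")
  expect_error(window_scheme("MONTH", "COVERED_FRACTION", 1.2),
               "covered_fraction")
})

test_that("window nesting: monthly max <= quarterly max <= annual count", {
  pop <- simulate_claims(sim_config(n_patients = 200, seed = 5))
  diary <- clip_diary(build_supply_diary(pop$refills, 2017))
  patients <- unique(diary$patient_id)
  mx <- function(g) {
    summarize_counts(count_per_window(diary, g, patients),
                     window_scheme(g, "MAX"))$summary_count
  }
  m <- mx("MONTH"); q <- mx("QUARTER"); a <- mx("ANNUAL")
  expect_true(all(m <= q))
  expect_true(all(q <= a))
  ## and the mean never exceeds the max
  me <- summarize_counts(count_per_window(diary, "MONTH", patients),
                         window_scheme("MONTH", "MEAN"))$summary_count
  expect_true(all(me <= m))
})

test_that("covered-fraction prevalence is non-increasing in the required fraction", {
  pop <- simulate_claims(sim_config(n_patients = 300, seed = 17))
  diary <- clip_diary(build_supply_diary(pop$refills, 2017))
  cnt <- count_per_window(diary, "MONTH", unique(diary$patient_id))
  prev <- vapply(c(0.5, 0.8, 1.0), function(f) {
    st <- summarize_counts(cnt, window_scheme("MONTH", "COVERED_FRACTION", f))
    prevalence(st, "poly5")$proportion
  }, numeric(1))
  expect_true(all(diff(prev) <= 0))
  ## and it is more conservative than the maximum rule
  pmax_ <- prevalence(summarize_counts(cnt, window_scheme("MONTH", "MAX")),
                      "poly5")$proportion
  expect_true(all(prev <= pmax_))
})

test_that("prevalence reporting uses half-up percentages over the cohort", {
  st <- data.table::data.table(
    patient_id = sprintf("p%03d", 1:8),
    summary_count = c(2, 3, 5, 6, 10, 12, 1, 9),
    poly5 = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    poly10 = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  st$class_bin <- factor(c("1-4", "1-4", "5", "6", ">=10", ">=10",
                           "1-4", "9"),
                         levels = c("1-4", "5", "6", "7", "8", "9", ">=10"))
  p5 <- prevalence(st, "poly5")
  expect_equal(p5$count, 5L)
  expect_equal(p5$percent, 62.5)
  expect_equal(prevalence(st, "poly10")$count, 2L)
  expect_equal(prevalence(st, ">=10")$count, 2L)
  expect_error(prevalence(st[0], "poly5"), "empty cohort")

  tab <- prevalence_by_class(st)
  expect_equal(nrow(tab), 7L)
  expect_equal(tab$count[tab$class_bin == "7"], 0L)
  expect_equal(sum(tab$count), 8L)

  expect_equal(prevalence_pct(1, 3), 33.33)
  expect_equal(prevalence_pct(1, 16), 6.25)
  expect_equal(prevalence_pct(1, 800), 0.13)  # 0.125 rounds half up
})

test_that("dispensing-only counting ignores coverage duration", {
  rf <- refill_row("p1", "2017-03-15", "C10AA05", n_pkg = 3, ddd = 30)
  disp <- count_dispensed_per_window(rf, "MONTH", 2017)
  expect_equal(disp$n_classes, c(0L, 0L, 1L, rep(0L, 9)))
  cov <- count_per_window(clip_diary(build_supply_diary(rf, 2017)), "MONTH")
  expect_equal(cov$n_classes, c(0L, 0L, 1L, 1L, 1L, 1L, rep(0L, 6)))
  ## annually both reduce to the distinct dispensed classes
  expect_equal(count_dispensed_per_window(rf, "ANNUAL", 2017)$n_classes,
               count_per_window(clip_diary(build_supply_diary(rf, 2017)),
                                "ANNUAL")$n_classes)
})
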