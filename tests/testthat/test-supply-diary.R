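test_that("days_supply follows the DDD rule with half-up rounding and a one-day floor", {
  expect_identical(days_supply(2, 28), 56L)
  expect_identical(days_supply(1, 0.4), 1L)
  expect_identical(days_supply(3, 16.5), 50L)  # 49.5 rounds half up
  expect_identical(days_supply(3, 16.5, rounding = "floor"), 49L)
  expect_identical(days_supply(1, 30.2, rounding = "ceil"), 31L)
  expect_error(days_supply(0, 28), "positive")
  expect_error(days_supply(1, -2), "positive")
})

test_that("same-class overlapping fills are shifted to abut; other classes overlap freely", {
  rf <- rbind(refill_row("p1", "2017-01-01", "C10AA05", ddd = 30),
              refill_row("p1", "2017-01-21", "C10AA07", ddd = 30))
  d <- build_supply_diary(rf)
  expect_equal(d$start_day, c(0L, 30L))
  expect_equal(d$end_day, c(30L, 60L))

  rf2 <- rbind(refill_row("p1", "2017-01-01", "C10AA05", ddd = 30),
               refill_row("p1", "2017-01-01", "A02BC01", ddd = 30))
  d2 <- build_supply_diary(rf2)
  expect_equal(d2$start_day, c(0L, 0L))  # cross-class overlap allowed
})

test_that("same-day same-class fills queue in record order", {
  rf <- rbind(refill_row("p1", "2017-03-01", "C10AA05", ddd = 10),
              refill_row("p1", "2017-03-01", "C10AA05", ddd = 20))
  rf$record_id <- c(2L, 1L)
  d <- build_supply_diary(rf)
  expect_equal(d$record_id, c(1L, 2L))
  expect_equal(d$start_day, c(59L, 79L))
  expect_equal(d$end_day - d$start_day, c(20L, 10L))
})

test_that("clipping keeps the in-period portion and drops empty segments", {
  rf <- rbind(refill_row("p1", "2016-12-22", "C10AA05", ddd = 15),
              refill_row("p1", "2016-06-01", "A02BC01", ddd = 30))
  d <- build_supply_diary(rf, 2017)
  clipped <- clip_diary(d)
  expect_equal(nrow(clipped), 1L)  # the mid-2016 fill never reaches 2017
  expect_equal(clipped$atc4, "C10AA")
  expect_equal(clipped$start_day, 0L)  # [-10, 5) clipped to [0, 5)
  expect_equal(clipped$end_day, 5L)
  expect_error(clip_diary(d, 10L, 5L), "period_end")
})

test_that("a December fill with 60-day supply carries coverage into the next year", {
  rf <- refill_row("p1", "2016-12-01", "C10AA05", n_pkg = 2, ddd = 30)
  d <- clip_diary(build_supply_diary(rf, 2017))
  expect_gte(sum(d$end_day - d$start_day), 1L)
  expect_equal(d$start_day, 0L)
  expect_equal(d$end_day, 29L)  # Dec 1 + 60 days = Jan 30 exclusive
})

test_that("covered_days does calendar arithmetic per window and returns 0 for absent classes", {
  rf <- refill_row("p1", "2017-01-25", "C10AA05", ddd = 12)
  d <- build_supply_diary(rf)  # covers 25 Jan - 5 Feb
  expect_equal(covered_days(d, "C10AA", "MONTH", 1L)$days, 7L)
  expect_equal(covered_days(d, "C10AA", "MONTH", 2L)$days, 5L)
  expect_equal(covered_days(d, "C10AA", "MONTH", 3L)$days, 0L)
  expect_equal(covered_days(d, "C10AA", "QUARTER", 1L)$days, 12L)
  expect_equal(covered_days(d, "N05BA", "ANNUAL", 1L)$days, 0L)

  full <- refill_row("p1", "2017-01-01", "C10AA05", ddd = 365)
  expect_equal(covered_days(build_supply_diary(full), "C10AA")$days, 365L)
})

test_that("diary equals the day-stack oracle on randomized fills and conserves supply", {
  set.seed(42)
  for (rep in 1:40) {
    rf <- random_refills(sample(1:20, 1))
    d <- build_supply_diary(rf)
    ## conservation: total segment length = total days supply, per class
    rf$ds <- days_supply(rf$n_packages, rf$ddd_per_package)
    rf$atc4 <- substr(rf$atc_code, 1, 5)
    for (cls in unique(rf$atc4)) {
      seg <- d[d$atc4 == cls, ]
      expect_identical(sum(seg$end_day - seg$start_day),
                       sum(rf$ds[rf$atc4 == cls]))
      ## non-overlap and sortedness
      if (nrow(seg) > 1L) {
        expect_true(all(seg$start_day[-1] >= seg$end_day[-nrow(seg)]))
      }
      ## oracle equivalence
      days <- as.integer(as.Date(rf$dispense_date[rf$atc4 == cls]) -
                           as.Date("2017-01-01"))
      expect_identical(diary_covered_set(d, cls),
                       oracle_covered_set(days, rf$ds[rf$atc4 == cls]))
    }
  }
})

test_that("the diary is invariant to input row order", {
  set.seed(99)
  for (rep in 1:10) {
    rf <- random_refills(15)
    perm <- rf[sample(nrow(rf)), ]
    expect_equal(build_supply_diary(rf), build_supply_diary(perm))
  }
})

test_that("without same-class overlap the diary is the naive per-fill intervals", {
  rf <- rbind(refill_row("p1", "2017-01-01", "C10AA05", ddd = 20),
              refill_row("p1", "2017-02-15", "C10AA05", ddd = 20),
              refill_row("p1", "2017-06-01", "A02BC01", ddd = 10))
  d <- build_supply_diary(rf)
  day <- as.integer(as.Date(rf$dispense_date) - as.Date("2017-01-01"))
  setkey(d, record_id)
  expect_equal(d$start_day, day)
  expect_equal(d$end_day, day + c(20L, 20L, 10L))
})

test_that("a finite stockpiling cap drops refills shifted beyond it", {
  rf <- do.call(rbind, lapply(1:3, function(i)
    refill_row("p1", "2017-01-01", "C10AA05", ddd = 30)))
  rf$record_id <- 1:3
  d0 <- build_supply_diary(rf)                       # unlimited: chained
  dc <- build_supply_diary(rf, max_shift_days = 10)  # later fills dropped
  expect_equal(nrow(d0), 3L)
  expect_equal(max(d0$end_day), 90L)
  expect_equal(nrow(dc), 1L)
  expect_equal(dc$end_day, 30L)
})

test_that("malformed refill input is rejected", {
  rf <- refill_row("p1", "2017-01-01", "C10AA05")
  expect_error(build_supply_diary(rf[, -3]), "missing column")
  rf_bad <- rf; rf_bad$n_packages <- 0
  expect_error(build_supply_diary(rf_bad), "positive")
  rf_short <- rf; rf_short$atc_code <- "C10"
  expect_error(build_supply_diary(rf_short), "5 characters")
})
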