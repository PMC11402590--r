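test_that("steps bin into half-open minute slots and counts are conserved", {
  s <- steps_per_minute(numeric(0), 0, 1)
  expect_true(all(s$counts == 0))

  s <- steps_per_minute(c(60.1, 60.5, 119.9), 0, 1)
  expect_equal(s$counts[1, 2], 3)
  expect_equal(sum(s$counts), 3)

  set.seed(41)
  tt <- sort(runif(200, 0, 86400 * 2 - 1))
  s2 <- steps_per_minute(tt, 0, 2)
  expect_equal(sum(s2$counts), 200)
})

test_that("nonwear is a stationary episode of at least an hour", {
  fs <- 10
  set.seed(42)
  noisy <- function(mins) matrix(rnorm(mins * 60 * fs * 3, sd = 0.02), ncol = 3) +
    matrix(rep(c(0, 0, 1), each = mins * 60 * fs), ncol = 3)
  const <- function(mins) matrix(rep(c(0, 0, 1), each = mins * 60 * fs), ncol = 3)

  # 2 h exactly constant: all 120 minutes nonwear
  rec <- accel_recording(const(120), fs)
  expect_equal(sum(!detect_nonwear(rec)), 120)
  # 30-min stationary block flanked by movement stays worn
  rec2 <- accel_recording(rbind(noisy(40), const(30), noisy(40)), fs)
  expect_true(all(detect_nonwear(rec2)))
  # vigorous gait is worn
  set.seed(43)
  sim <- simulate_walk_bout(gait_profile(), 180, fs)
  expect_true(all(detect_nonwear(accel_recording(sim$samples, fs))))
})

test_that("imputation averages the same minute of day over worn days only", {
  counts <- matrix(0, 3, 1440)
  worn <- matrix(TRUE, 3, 1440)
  counts[1, 601] <- 30; counts[3, 601] <- 50
  worn[2, 601] <- FALSE
  s <- minute_series(counts, worn)
  imp <- impute_nonwear(s)
  expect_equal(imp$counts[2, 601], 40)
  expect_true(imp$imputed[2, 601])
  # worn slots never altered
  expect_identical(imp$counts[worn], s$counts[worn])
  # no nonwear: identity
  s0 <- minute_series(counts)
  expect_identical(impute_nonwear(s0)$counts, s0$counts)
  # slot worn nowhere: imputed 0 with warning
  worn2 <- worn; worn2[, 601] <- FALSE
  expect_warning(imp2 <- impute_nonwear(minute_series(counts, worn2)),
                 "worn on no day")
  expect_true(all(imp2$counts[, 601] == 0))
  # conservation: imputation only adds steps
  expect_gte(sum(imp$counts), sum(s$counts))
})

test_that("median daily steps and peak cadence follow their definitions", {
  mk <- function(totals, peak = NULL) {
    counts <- matrix(0, length(totals), 1440)
    for (d in seq_along(totals)) counts[d, 1] <- totals[d]
    if (!is.null(peak)) for (d in seq_along(peak)) counts[d, 700] <- peak[d]
    minute_series(counts)
  }
  expect_equal(median_daily_steps(mk(c(8000, 9000, 10000))), 9000)
  expect_equal(median_daily_steps(mk(c(8000, 10000))), 9000)
  expect_equal(median_daily_steps(mk(c(7500, 7500, 7500))), 7500)

  expect_equal(peak_1min_cadence(mk(c(0, 0), peak = c(110, 120))), 115)
  expect_equal(peak_1min_cadence(mk(0, peak = 120)), 120)
  # adding a minute below the daily max changes nothing
  s <- mk(c(0, 0), peak = c(110, 120))
  s$counts[1, 3] <- 50
  expect_equal(peak_1min_cadence(s), 115)
})

test_that("QC boundaries: 72 h and 100 mg pass; below/above flag", {
  full <- rep(TRUE, 24)
  expect_false(any(qc_checks(80, full, 28)))
  expect_true(qc_checks(71.9, full, 28)["insufficient_wear"])
  expect_false(qc_checks(72.0, full, 28)["insufficient_wear"])
  expect_false(qc_checks(80, full, 100)["implausible_acceleration"])
  expect_true(qc_checks(80, full, 150)["implausible_acceleration"])
  gap <- full; gap[4] <- FALSE
  expect_true(qc_checks(80, gap, 28)["diurnal_gap"])
  # calibration flag exists but is never set here
  expect_false(qc_checks(10, gap, 500)["poor_calibration"])
})

test_that("daily_summary composes imputation, medians and QC", {
  counts <- matrix(0, 2, 1440)
  counts[1, 500] <- 100; counts[2, 500] <- 60
  worn <- matrix(TRUE, 2, 1440); worn[2, 600:659] <- FALSE
  ds <- daily_summary(minute_series(counts, worn), mean_acceleration_mg = 28)
  expect_equal(ds$median_daily_steps, 80)
  expect_equal(ds$peak_1min_cadence, 80)
  expect_true(ds$qc_flags["insufficient_wear"])  # only 2 days of wear-minutes
  expect_equal(ds$wear_hours, (2 * 1440 - 60) / 60)
})
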