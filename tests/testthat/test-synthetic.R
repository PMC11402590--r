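test_that("zero jitter gives exactly the nominal step count", {
  set.seed(61)
  sim <- simulate_walk_bout(gait_profile(cadence_spm = 100, cadence_jitter = 0),
                            60, 25)
  expect_length(sim$step_times, 100L)
  expect_true(all(diff(sim$step_times) > 0))
})

test_that("clean walking is recovered step-for-step by the detector", {
  set.seed(62)
  sim <- simulate_walk_bout(gait_profile(noise_sd_g = 0), 60, 25)
  vm <- conditioned_vm(sim$samples, 25)
  pk <- find_peaks_1d(vm, 25, detector_params(0.2, 0.4, 1.0))
  expect_equal(length(pk), length(sim$step_times))
})

test_that("the device orientation does not affect the conditioned VM", {
  pr0 <- gait_profile(noise_sd_g = 0, orientation = diag(3))
  set.seed(63)
  R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
  pr1 <- gait_profile(noise_sd_g = 0, orientation = R)
  set.seed(64); a <- simulate_walk_bout(pr0, 30, 25)
  set.seed(64); b <- simulate_walk_bout(pr1, 30, 25)
  expect_equal(conditioned_vm(a$samples, 25), conditioned_vm(b$samples, 25),
               tolerance = 1e-9)
  expect_equal(a$step_times, b$step_times)
})

test_that("non-walking bouts yield no detectable steps at grid parameters", {
  set.seed(65)
  sed <- simulate_nonwalk_bout("sedentary", 120, 25)
  fid <- simulate_nonwalk_bout("fidget", 120, 25)
  prm <- detector_params(0.1, 0.2, 1.0)
  expect_length(find_peaks_1d(conditioned_vm(sed, 25), 25, prm), 0L)
  expect_length(find_peaks_1d(conditioned_vm(fid, 25), 25, prm), 0L)
  # nonwear: exactly constant -> flagged by detect_nonwear
  nw <- simulate_nonwalk_bout("nonwear", 3900, 25)
  worn <- detect_nonwear(accel_recording(nw, 25))
  expect_true(all(!worn))
})

test_that("simulated participants carry self-consistent ground truth", {
  sr <- simulate_participant(list(
    list(kind = "sedentary", duration_s = 70),
    list(kind = "walk", duration_s = 125),
    list(kind = "fidget", duration_s = 65),
    list(kind = "walk", duration_s = 90,
         profile = gait_profile(cadence_spm = 85))), seed = 66)
  ep <- epoch_split(sr$recording)
  expect_identical(label_epochs_from_steps(sr$truth_steps, ep),
                   sr$truth_labels)
  # all-nonwalk plan
  sr0 <- simulate_participant(list(list(kind = "sedentary", duration_s = 60)),
                              seed = 67)
  expect_equal(nrow(sr0$truth_steps), 0L)
  expect_true(all(sr0$truth_labels == "nonwalk"))
  # determinism: same seed, same bits
  sr2 <- simulate_participant(list(
    list(kind = "walk", duration_s = 60)), seed = 68)
  sr3 <- simulate_participant(list(
    list(kind = "walk", duration_s = 60)), seed = 68)
  expect_identical(sr2$recording$samples, sr3$recording$samples)
  expect_identical(sr2$truth_steps, sr3$truth_steps)
})

test_that("fixture cohorts regenerate byte-identically from the same seed", {
  d1 <- file.path(tempdir(), "ws_regen1")
  d2 <- file.path(tempdir(), "ws_regen2")
  make_fixture_cohort(2, "clemson_like", seed = 9, dir = d1)
  make_fixture_cohort(2, "clemson_like", seed = 9, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # cohort shape: one ~37-min recording per participant
  rec <- read_recording(file.path(d1, "C01.csv"))
  expect_gt(duration_s(rec) / 60, 25)
  expect_lt(duration_s(rec) / 60, 50)
})

test_that("week-long plans leave imputation donors for every nonwear minute", {
  sr <- simulate_participant(plan_week_for_test(days = 3), sample_rate_hz = 5,
                             seed = 70)
  worn <- matrix(sr$truth_wear, nrow = 3, byrow = TRUE)
  # nonwear exists, and every minute-of-day is worn on some day
  expect_gt(sum(!worn), 0)
  expect_true(all(colSums(worn) >= 1))
})
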