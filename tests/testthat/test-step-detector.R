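test_that("peak detection on canonical signals", {
  prm <- detector_params(0.3, 0.3, 1.0)
  expect_length(find_peaks_1d(rep(0, 100), 25, prm), 0L)
  # 0.5 g, 2 Hz sinusoid over 10 s at 25 Hz: one peak per cycle
  v <- 0.5 * sin(2 * pi * 2 * (0:249) / 25)
  expect_length(find_peaks_1d(v, 25, prm), 20L)
})

test_that("the taller of two close peaks wins the distance constraint", {
  fs <- 100
  v <- rep(0, 60)
  v[20] <- 1.0
  v[30] <- 0.8   # 0.1 s away
  got <- find_peaks_1d(v, fs, suppressWarnings(detector_params(0.1, 0.2, 10)))
  expect_identical(got, 20L)
  # with a permissive distance both survive
  got2 <- find_peaks_1d(v, fs, suppressWarnings(detector_params(0.1, 0.05, 10)))
  expect_identical(got2, c(20L, 30L))
})

test_that("width is a maximum bound by default, a minimum on request", {
  fs <- 25
  t <- (0:499) / fs
  v <- 0.5 * sin(2 * pi * 0.5 * t)   # broad peaks: half-prominence width 0.67 s
  narrow_max <- suppressWarnings(detector_params(0.2, 0.2, 0.4, "max"))
  expect_length(find_peaks_1d(v, fs, narrow_max), 0L)
  narrow_min <- suppressWarnings(detector_params(0.2, 0.2, 0.4, "min"))
  expect_gt(length(find_peaks_1d(v, fs, narrow_min)), 0L)
})

test_that("raising prominence or distance never increases the peak count", {
  set.seed(31)
  for (i in 1:20) {
    v <- butterworth_lowpass(rnorm(400, sd = 0.5), 25, cutoff_hz = 6)
    n1 <- length(find_peaks_1d(v, 25, detector_params(0.1, 0.2, 1)))
    n2 <- length(find_peaks_1d(v, 25, detector_params(0.3, 0.2, 1)))
    n3 <- length(find_peaks_1d(v, 25, detector_params(0.1, 0.6, 1)))
    expect_lte(n2, n1)
    expect_lte(n3, n1)
  }
})

test_that("find_peaks_1d agrees with the brute-force oracle on random signals", {
  set.seed(32)
  for (i in 1:25) {
    v <- cumsum(rnorm(300, sd = 0.1))
    v <- v - butterworth_lowpass(v, 25, cutoff_hz = 0.5)
    p <- runif(1, 0.05, 0.5); d <- runif(1, 0.1, 1.5); w <- runif(1, 0.05, 1)
    got <- find_peaks_1d(v, 25, suppressWarnings(detector_params(p, d, w)))
    expect_identical(got, oracle_find_peaks(v, 25, p, d, w))
  }
})

test_that("detect_steps gates on walking labels and preserves bout counts", {
  set.seed(33)
  prm <- detector_params(0.2, 0.4, 1.0)
  sr <- simulate_participant(list(
    list(kind = "sedentary", duration_s = 30),
    list(kind = "walk", duration_s = 60,
         profile = gait_profile(cadence_spm = 100, cadence_jitter = 0)),
    list(kind = "sedentary", duration_s = 30)), seed = 77)
  # all non-walk: zero steps regardless of signal
  none <- detect_steps(sr$recording, rep("nonwalk", length(sr$truth_labels)), prm)
  expect_equal(nrow(none), 0L)
  # truth labels: ~100 steps at cadence 100 over 60 s
  st <- detect_steps(sr$recording, sr$truth_labels, prm)
  expect_lte(abs(nrow(st) - nrow(sr$truth_steps)), 2)
  expect_true(all(diff(st$time_s) > 0))
  # per-epoch counting differs from run-concatenated by at most one step per
  # epoch boundary inside walking runs
  st_pe <- detect_steps(sr$recording, sr$truth_labels, prm, per_epoch = TRUE)
  n_boundaries <- sum(sr$truth_labels == "walk") - 1
  expect_lte(abs(nrow(st) - nrow(st_pe)), n_boundaries)
  expect_error(detect_steps(sr$recording, rep("walk", 3), prm), "align")
})

test_that("tuning returns the unique zero-error cell when one exists", {
  set.seed(34)
  sim <- simulate_walk_bout(gait_profile(cadence_spm = 110, cadence_jitter = 0,
                                         noise_sd_g = 0), 30, 25)
  item <- list(vm = conditioned_vm(sim$samples, 25), sample_rate_hz = 25,
               true_count = length(sim$step_times))
  grid <- data.frame(prominence_g = c(0.2, 0.9), distance_s = c(0.4, 1.8),
                     width_s = c(1, 1))
  sel <- tune_detector(list(item), grid)
  expect_equal(sel$prominence_g, 0.2)
  expect_equal(attr(sel, "mae"), 0)
  expect_error(tune_detector(list(), grid), "empty validation")
  expect_error(tune_detector(list(item), grid[0, ]), "empty grid")
})

test_that("step events must be strictly increasing", {
  expect_error(step_events(c(1, 1, 2)), "strictly increasing")
  expect_silent(step_events(c(0.5, 1.2, 3)))
})
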