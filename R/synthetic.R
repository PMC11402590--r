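# Synthetic wrist-like recordings with known per-step ground truth: the
# package's test bed. Walking bouts are half-sine step impulses on the body
# vertical axis plus an arm-swing sinusoid at half the step frequency, with
# gravity, an arbitrary fixed device orientation per bout, and Gaussian
# sensor noise. Non-walking bouts are sedentary noise, sparse low-prominence
# fidget transients, or exactly constant gravity (nonwear).

#' Gait profile for the simulator
#'
#' @param cadence_spm walking cadence in steps per minute (40-200).
#' @param cadence_jitter coefficient of variation of the inter-step interval.
#' @param step_impulse_g amplitude of the per-step half-sine impulse (g).
#' @param arm_swing_ratio arm-swing sinusoid amplitude relative to
#'   `step_impulse_g`.
#' @param noise_sd_g per-axis Gaussian sensor noise SD (g).
#' @param orientation optional fixed 3x3 rotation applied to the whole bout;
#'   `NULL` draws a random orientation.
#' @return an object of class `gait_profile`.
#' @export
gait_profile <- function(cadence_spm = 110, cadence_jitter = 0.05,
                         step_impulse_g = 0.5, arm_swing_ratio = 0.3,
                         noise_sd_g = 0.03, orientation = NULL) {
  stopifnot(cadence_spm >= 40, cadence_spm <= 200, cadence_jitter >= 0,
            step_impulse_g >= 0, arm_swing_ratio >= 0, noise_sd_g >= 0)
  structure(list(cadence_spm = cadence_spm, cadence_jitter = cadence_jitter,
                 step_impulse_g = step_impulse_g,
                 arm_swing_ratio = arm_swing_ratio, noise_sd_g = noise_sd_g,
                 orientation = orientation),
            class = "gait_profile")
}

random_orientation <- function() rotation_matrix(stats::rnorm(3),
                                                 stats::runif(1, 0, 2 * pi))

#' Simulate one walking bout
#'
#' Inter-step intervals are `60 / cadence * (1 + jitter * z)` (truncated at
#' 30% of the nominal interval); each step adds a half-sine impulse centred
#' on its timestamp to the body vertical axis; an arm-swing sinusoid at half
#' the step frequency is added to a horizontal axis; gravity is added, the
#' bout orientation applied, and Gaussian noise added. With zero jitter a
#' bout of `duration_s` at cadence `c` contains exactly
#' `floor((duration_s - 30/c) / (60/c)) + 1` steps.
#'
#' @param profile a [gait_profile()].
#' @param duration_s bout duration in seconds.
#' @param sample_rate_hz sampling rate in Hz.
#' @return list with `samples` (matrix, n x 3, g) and `step_times` (exact
#'   step timestamps in seconds from the bout start).
#' @export
simulate_walk_bout <- function(profile, duration_s, sample_rate_hz) {
  stopifnot(duration_s > 0)
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  base <- 60 / profile$cadence_spm
  # step timestamps
  t_steps <- numeric(0)
  t <- base / 2
  while (t < duration_s) {
    t_steps <- c(t_steps, t)
    gap <- base * (1 + profile$cadence_jitter * stats::rnorm(1))
    t <- t + max(gap, 0.3 * base)
  }
  tt <- (seq_len(n) - 1) / fs
  vert <- numeric(n)
  w <- min(0.3, 0.7 * base)               # impulse width (s)
  for (ts in t_steps) {
    i0 <- max(1L, ceiling((ts - w / 2) * fs) + 1L)
    i1 <- min(n, floor((ts + w / 2) * fs) + 1L)
    if (i1 >= i0) {
      u <- tt[i0:i1] - (ts - w / 2)
      vert[i0:i1] <- vert[i0:i1] + profile$step_impulse_g * sin(pi * u / w)
    }
  }
  swing <- profile$arm_swing_ratio * profile$step_impulse_g *
    sin(2 * pi * (profile$cadence_spm / 120) * tt)
  body <- cbind(swing, 0, 1 + vert)
  R <- profile$orientation %||% random_orientation()
  samples <- body %*% t(R)
  if (profile$noise_sd_g > 0)
    samples <- samples + matrix(stats::rnorm(3 * n, sd = profile$noise_sd_g),
                                n, 3)
  list(samples = samples, step_times = t_steps)
}

#' Simulate one non-walking bout
#'
#' `sedentary`: gravity in a random fixed orientation plus sensor noise
#' (default 20 mg SD -- above the 13 mg stationarity threshold, so sedentary
#' time is worn). `fidget`: sedentary plus sparse low-amplitude transients
#' whose conditioned prominence stays below the 0.1 g tuning-grid floor.
#' `nonwear`: exactly constant gravity (zero variance), so stationary
#' episodes are detected by [detect_nonwear()].
#'
#' @param kind one of `"sedentary"`, `"fidget"`, `"nonwear"`.
#' @param duration_s bout duration in seconds.
#' @param sample_rate_hz sampling rate in Hz.
#' @param noise_sd_g sensor noise SD for worn bouts (g).
#' @return matrix of triaxial samples (n x 3, g).
#' @export
simulate_nonwalk_bout <- function(kind = c("sedentary", "fidget", "nonwear"),
                                  duration_s, sample_rate_hz,
                                  noise_sd_g = 0.02) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0)
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  R <- random_orientation()
  body <- cbind(rep(0, n), 0, rep(1, n))
  if (kind == "fidget") {
    # transient amplitude plus filtered noise excursions stays below the
    # 0.1 g prominence floor of the detector tuning grid by construction
    noise_sd_g <- min(noise_sd_g, 0.012)
    n_ev <- stats::rpois(1, 0.15 * duration_s)
    tt <- (seq_len(n) - 1) / fs
    for (ev in seq_len(n_ev)) {
      ts <- stats::runif(1, 0.2, duration_s - 0.2)
      amp <- stats::runif(1, 0.015, 0.035)
      wd <- 0.2
      i0 <- max(1L, ceiling((ts - wd / 2) * fs) + 1L)
      i1 <- min(n, floor((ts + wd / 2) * fs) + 1L)
      if (i1 >= i0) {
        u <- tt[i0:i1] - (ts - wd / 2)
        body[i0:i1, 3] <- body[i0:i1, 3] + amp * sin(pi * u / wd)
      }
    }
  }
  samples <- body %*% t(R)
  if (kind != "nonwear")
    samples <- samples + matrix(stats::rnorm(3 * n, sd = noise_sd_g), n, 3)
  samples
}

#' Simulate a participant from a bout plan
#'
#' Concatenates walking and non-walking bouts into one recording and derives
#' the ground truth: exact step timestamps, per-epoch walk labels (via the
#' at-least-four-steps rule), and the per-minute wear mask (a minute is
#' nonwear iff it lies entirely inside nonwear bouts). Fully reproducible
#' from `seed`.
#'
#' @param plan list of bouts; each a list with `kind` (`"walk"`,
#'   `"sedentary"`, `"fidget"`, `"nonwear"`), `duration_s`, and for walking
#'   bouts an optional `profile` ([gait_profile()]).
#' @param sample_rate_hz sampling rate in Hz (default 25).
#' @param participant_id recording id.
#' @param start_time recording start in seconds since local midnight.
#' @param epoch_length_s epoch length for the truth labels (default 10).
#' @param seed optional integer seed.
#' @return an object of class `synthetic_recording`: `recording`
#'   (`accel_recording`), `truth_steps` ([step_events()]), `truth_labels`
#'   (per-epoch factor), `truth_wear` (per-minute logical).
#' @export
simulate_participant <- function(plan, sample_rate_hz = 25,
                                 participant_id = "P01", start_time = 0,
                                 epoch_length_s = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- sample_rate_hz
  chunks <- vector("list", length(plan))
  steps <- numeric(0)
  nonwear_iv <- NULL
  t_at <- 0
  for (b in seq_along(plan)) {
    bout <- plan[[b]]
    if (bout$kind == "walk") {
      pr <- bout$profile %||% gait_profile()
      sim <- simulate_walk_bout(pr, bout$duration_s, fs)
      chunks[[b]] <- sim$samples
      steps <- c(steps, t_at + sim$step_times)
    } else {
      chunks[[b]] <- simulate_nonwalk_bout(bout$kind, bout$duration_s, fs,
                                           noise_sd_g = bout$noise_sd_g %||% 0.02)
      if (bout$kind == "nonwear")
        nonwear_iv <- rbind(nonwear_iv, c(t_at, t_at + bout$duration_s))
    }
    t_at <- t_at + nrow(chunks[[b]]) / fs
  }
  samples <- do.call(rbind, chunks)
  rec <- accel_recording(samples, fs, start_time, participant_id)
  epochs <- epoch_split(rec, epoch_length_s)
  labels <- label_epochs_from_steps(steps, epochs)
  n_min <- nrow(samples) %/% round(60 * fs)
  wear <- rep(TRUE, n_min)
  for (r in seq_len(NROW(nonwear_iv))) {
    m0 <- ceiling(nonwear_iv[r, 1] / 60)          # first minute fully inside
    m1 <- floor(nonwear_iv[r, 2] / 60) - 1L       # last minute fully inside
    if (m1 >= m0) wear[(m0:m1) + 1L] <- FALSE
  }
  structure(list(recording = rec,
                 truth_steps = step_events(
                   steps, as.integer(steps %/% epoch_length_s) + 1L),
                 truth_labels = labels,
                 truth_wear = wear),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %s: %.1f s, %d true steps, %d/%d walk epochs\n",
              x$recording$participant_id, duration_s(x$recording),
              nrow(x$truth_steps), sum(x$truth_labels == "walk"),
              length(x$truth_labels)))
  invisible(x)
}

# --- bout plans for the three presets ---------------------------------------

# ~1 h of mixed free living: alternating sedentary / walking bouts with
# occasional fidgeting, cadences 90-130 steps/min.
plan_oxwalk <- function(total_s = 3600) {
  plan <- list()
  t <- 0
  while (t < total_s) {
    sed <- min(stats::runif(1, 60, 240), total_s - t)
    plan[[length(plan) + 1L]] <- list(kind = "sedentary", duration_s = sed)
    t <- t + sed
    if (t >= total_s) break
    if (stats::runif(1) < 0.25) {
      fid <- min(stats::runif(1, 60, 180), total_s - t)
      plan[[length(plan) + 1L]] <- list(kind = "fidget", duration_s = fid)
      t <- t + fid
      if (t >= total_s) break
    }
    wk <- min(stats::runif(1, 60, 240), total_s - t)
    plan[[length(plan) + 1L]] <- list(
      kind = "walk", duration_s = wk,
      profile = gait_profile(cadence_spm = stats::runif(1, 90, 130),
                             step_impulse_g = stats::runif(1, 0.4, 0.6)))
    t <- t + wk
  }
  plan
}

# Three lab-style sessions (~37 min): regular, semiregular, irregular walking.
plan_clemson <- function() {
  plan <- list(
    list(kind = "walk", duration_s = 720,
         profile = gait_profile(cadence_spm = 110, cadence_jitter = 0.03)),
    list(kind = "sedentary", duration_s = 60)
  )
  for (i in 1:6) {
    plan[[length(plan) + 1L]] <- list(
      kind = "walk", duration_s = stats::runif(1, 60, 120),
      profile = gait_profile(cadence_spm = stats::runif(1, 95, 120),
                             cadence_jitter = 0.08))
    plan[[length(plan) + 1L]] <- list(kind = "sedentary",
                                      duration_s = stats::runif(1, 10, 30))
  }
  t <- 0
  while (t < 700) {
    wk <- stats::runif(1, 20, 45)
    plan[[length(plan) + 1L]] <- list(
      kind = "walk", duration_s = wk,
      profile = gait_profile(cadence_spm = stats::runif(1, 70, 95),
                             cadence_jitter = 0.12))
    sed <- stats::runif(1, 15, 45)
    plan[[length(plan) + 1L]] <- list(kind = "sedentary", duration_s = sed)
    t <- t + wk + sed
  }
  plan
}

# Multi-day wear: overnight sedentary, hourly daytime walking bouts, and one
# 2-h nonwear gap on `nonwear_day` (14:00-16:00) so that every nonwear minute
# has imputation donors on the other days.
plan_week <- function(days = 7, nonwear_day = min(3L, days)) {
  plan <- list()
  for (d in seq_len(days)) {
    plan[[length(plan) + 1L]] <- list(kind = "sedentary", duration_s = 7 * 3600)
    for (h in 7:21) {
      if (d == nonwear_day && h %in% 14:15) {
        plan[[length(plan) + 1L]] <- list(kind = "nonwear", duration_s = 3600)
        next
      }
      wk <- stats::runif(1, 240, 420)
      plan[[length(plan) + 1L]] <- list(
        kind = "walk", duration_s = wk,
        profile = gait_profile(cadence_spm = stats::runif(1, 95, 120)))
      plan[[length(plan) + 1L]] <- list(kind = "sedentary",
                                        duration_s = 3600 - wk)
    }
    plan[[length(plan) + 1L]] <- list(kind = "sedentary", duration_s = 2 * 3600)
  }
  plan
}

#' Generate a deterministic synthetic cohort
#'
#' Presets mirror the shapes of the datasets the pipeline is meant for:
#' `oxwalk_like` = ~1 h of mixed free living per participant at 25 Hz;
#' `clemson_like` = three lab sessions (regular / semiregular / irregular
#' walking, ~37 min) at 15 Hz; `week_long` = multi-day continuous wear with a
#' nonwear gap at 15 Hz. Each participant gets an independent substream
#' derived from `seed` via [derive_seed()], so cohorts are reproducible
#' file-for-file.
#'
#' @param n_participants number of participants.
#' @param preset `"oxwalk_like"`, `"clemson_like"` or `"week_long"`.
#' @param seed integer master seed.
#' @param dir optional directory; when given, per-participant CSV fixtures
#'   are written (`<id>.csv` recording, `<id>_steps.csv`, `<id>_labels.csv`,
#'   `<id>_wear.csv`).
#' @param sample_rate_hz override the preset's sampling rate.
#' @param days number of days for the `week_long` preset.
#' @return list of [simulate_participant()] results, invisibly when `dir` is
#'   given.
#' @export
make_fixture_cohort <- function(n_participants,
                                preset = c("oxwalk_like", "clemson_like",
                                           "week_long"),
                                seed = 1L, dir = NULL, sample_rate_hz = NULL,
                                days = 7L) {
  preset <- match.arg(preset)
  stopifnot(n_participants >= 1)
  fs <- sample_rate_hz %||% switch(preset, oxwalk_like = 25, clemson_like = 15,
                                   week_long = 15)
  ids <- sprintf("%s%02d", toupper(substr(preset, 1, 1)), seq_len(n_participants))
  out <- lapply(ids, function(id) {
    s <- derive_seed(seed, id)
    set.seed(s)
    plan <- switch(preset, oxwalk_like = plan_oxwalk(),
                   clemson_like = plan_clemson(), week_long = plan_week(days))
    simulate_participant(plan, sample_rate_hz = fs, participant_id = id,
                         seed = derive_seed(s, "samples"))
  })
  names(out) <- ids
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (sr in out) write_synthetic_recording(sr, dir)
  }
  if (is.null(dir)) out else invisible(out)
}

#' Write a synthetic recording and its ground truth as CSV fixtures
#'
#' @param sr a `synthetic_recording`.
#' @param dir output directory.
#' @return the recording CSV path, invisibly.
#' @export
write_synthetic_recording <- function(sr, dir) {
  id <- sr$recording$participant_id
  path <- file.path(dir, paste0(id, ".csv"))
  write_recording(sr$recording, path)
  data.table::fwrite(data.table::data.table(time_s = sr$truth_steps$time_s),
                     file.path(dir, paste0(id, "_steps.csv")))
  data.table::fwrite(data.table::data.table(
    epoch_index = seq_along(sr$truth_labels),
    label = as.character(sr$truth_labels)),
    file.path(dir, paste0(id, "_labels.csv")))
  data.table::fwrite(data.table::data.table(
    minute = seq_along(sr$truth_wear) - 1L, worn = sr$truth_wear),
    file.path(dir, paste0(id, "_wear.csv")))
  invisible(path)
}
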