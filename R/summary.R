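# Daily summaries: per-minute step counts with a wear mask, stationary
# nonwear detection, time-of-day imputation, median daily steps, one-minute
# peak cadence, and wear quality control.

#' Per-minute step-count series
#'
#' A days x 1440 matrix of per-minute step counts aligned to local clock
#' midnight, with a parallel wear mask (`TRUE` = worn). Nonwear slots carry
#' no observed counts; they are filled by [impute_nonwear()].
#'
#' @param counts numeric matrix, days x 1440, step counts per minute.
#' @param worn logical matrix of the same shape (default: all worn).
#' @return an object of class `minute_series`.
#' @export
minute_series <- function(counts, worn = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 1440L) stop("counts must have 1440 minute columns")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(worn)) worn <- matrix(TRUE, nrow(counts), ncol(counts))
  worn <- as.matrix(worn)
  if (!identical(dim(worn), dim(counts))) stop("worn mask dimensions must match")
  structure(list(counts = counts, worn = worn,
                 imputed = matrix(FALSE, nrow(counts), ncol(counts))),
            class = "minute_series")
}

#' @export
print.minute_series <- function(x, ...) {
  cat(sprintf("<minute_series> %d day(s); %.1f wear hours; %d imputed minute(s)\n",
              nrow(x$counts), sum(x$worn) / 60, sum(x$imputed)))
  invisible(x)
}

#' Bin step events into per-minute counts
#'
#' Counts step timestamps into half-open `[minute, minute + 1)` slots on a
#' day grid anchored at the local midnight preceding `start_time_s`.
#'
#' @param step_times numeric step times in seconds relative to the recording
#'   start (or a [step_events()] object).
#' @param start_time_s recording start in seconds since local midnight of an
#'   arbitrary day 0.
#' @param n_days number of days in the grid; defaults to the span of the
#'   steps (minimum 1).
#' @param worn optional logical wear mask aligned to the grid, either a
#'   days x 1440 matrix or a vector of per-minute values starting at the
#'   recording start minute (as returned by [detect_nonwear()]).
#' @return a [minute_series()].
#' @export
steps_per_minute <- function(step_times, start_time_s = 0, n_days = NULL,
                             worn = NULL) {
  if (inherits(step_times, "step_events")) step_times <- step_times$time_s
  day0 <- floor(start_time_s / 86400) * 86400
  abs_t <- start_time_s + step_times
  if (is.null(n_days))
    n_days <- max(1L, ceiling((max(c(abs_t, start_time_s + 1e-9)) - day0) / 86400))
  minute <- floor((abs_t - day0) / 60)
  if (length(minute) && (any(minute < 0) || any(minute >= n_days * 1440)))
    stop("step times fall outside the day grid")
  counts <- matrix(0, n_days, 1440)
  if (length(minute)) {
    tab <- table(minute)
    idx <- as.integer(names(tab))
    counts[cbind(idx %/% 1440 + 1L, idx %% 1440 + 1L)] <- as.numeric(tab)
  }
  worn_mat <- matrix(TRUE, n_days, 1440)
  if (!is.null(worn)) {
    if (is.matrix(worn)) worn_mat <- worn
    else {
      offset <- floor((start_time_s - day0) / 60)
      j <- offset + seq_along(worn)
      j <- j[j <= n_days * 1440]
      worn_mat[cbind((j - 1L) %/% 1440 + 1L, (j - 1L) %% 1440 + 1L)] <-
        worn[seq_along(j)]
    }
  }
  minute_series(counts, worn_mat)
}

#' Detect nonwear minutes from a raw recording
#'
#' A minute is stationary when the rolling standard deviation of every axis
#' within it is below `sd_threshold_g` (default 13 mg); runs of at least
#' `min_episode_min` (default 60) consecutive stationary minutes are marked
#' nonwear. Shorter stationary blocks (e.g. sitting still) stay worn.
#'
#' @param recording an `accel_recording`.
#' @param sd_threshold_g per-axis SD threshold in g (default 0.013).
#' @param min_episode_min minimum stationary episode length in minutes.
#' @return logical vector, one value per complete minute of the recording
#'   (`TRUE` = worn).
#' @export
detect_nonwear <- function(recording, sd_threshold_g = 0.013,
                           min_episode_min = 60L) {
  fs <- recording$sample_rate_hz
  spm <- round(60 * fs)
  n_min <- nrow(recording$samples) %/% spm
  if (n_min == 0L) return(logical(0))
  stationary <- rep(TRUE, n_min)
  for (j in 1:3) {
    v <- recording$samples[seq_len(n_min * spm), j]
    m <- matrix(v, nrow = spm)
    mu <- colMeans(m)
    sdv <- sqrt(pmax(colMeans(m^2) - mu^2, 0) * spm / (spm - 1))
    stationary <- stationary & (sdv < sd_threshold_g)
  }
  worn <- rep(TRUE, n_min)
  runs <- label_runs(stationary)
  runs <- runs[runs$value & (runs$end - runs$start + 1L) >= min_episode_min, ,
               drop = FALSE]
  for (r in seq_len(nrow(runs))) worn[runs$start[r]:runs$end[r]] <- FALSE
  worn
}

#' Impute nonwear minutes from the same time of day
#'
#' Each nonwear slot is replaced by the mean count of the same minute-of-day
#' over all days where that slot was worn. Slots worn on no day are imputed
#' as 0 with a warning. Worn slots are never altered.
#'
#' @param series a [minute_series()].
#' @return the series with nonwear slots filled and `$imputed` marking them.
#' @export
impute_nonwear <- function(series) {
  counts <- series$counts; worn <- series$worn
  if (all(worn)) return(series)
  no_donor <- 0L
  for (m in which(colSums(!worn) > 0)) {
    donors <- worn[, m]
    val <- if (any(donors)) mean(counts[donors, m]) else {
      no_donor <- no_donor + 1L
      0
    }
    counts[!donors, m] <- val
  }
  if (no_donor > 0L)
    warning(sprintf("%d minute-of-day slot(s) worn on no day; imputed as 0",
                    no_donor))
  out <- series
  out$counts <- counts
  out$imputed <- !worn
  out
}

# Days eligible for the daily summaries: any day with >= 1 worn minute.
valid_days <- function(series) rowSums(series$worn) >= 1L

#' Median daily step count
#'
#' Median over valid days of the per-day totals of the (imputed) series. A
#' valid day is any day with at least one worn minute.
#'
#' @param series a [minute_series()], normally after [impute_nonwear()].
#' @return median daily steps.
#' @export
median_daily_steps <- function(series) {
  v <- valid_days(series)
  if (!any(v)) stop("no valid days")
  stats::median(rowSums(series$counts)[v])
}

#' One-minute peak cadence
#'
#' For each valid day, the maximum single-minute step count; returns the mean
#' of those daily maxima (steps per minute).
#'
#' @param series a [minute_series()].
#' @return peak 1-min cadence in steps per minute.
#' @export
peak_1min_cadence <- function(series) {
  v <- valid_days(series)
  if (!any(v)) stop("no valid days")
  mean(apply(series$counts[v, , drop = FALSE], 1, max))
}

#' Total wear time in hours
#' @param series a [minute_series()].
#' @return wear hours.
#' @export
wear_hours <- function(series) sum(series$worn) / 60

#' Wear quality-control flags
#'
#' Flags a recording for insufficient wear (< 72 h), a diurnal gap (any
#' hour of day with zero worn minutes across all days), or implausible
#' average acceleration (> 100 mg, strict). Boundary semantics: exactly 72 h
#' and exactly 100 mg pass. The device-calibration flag slot exists but is
#' never set by this package (calibration is an external step).
#'
#' @param wear_h total wear time in hours.
#' @param hours_covered logical vector of length 24: hour of day has at least
#'   one worn minute on some day.
#' @param mean_acceleration_mg mean gravity-removed vector magnitude in mg.
#' @return named logical vector of flags.
#' @export
qc_checks <- function(wear_h, hours_covered, mean_acceleration_mg) {
  stopifnot(length(hours_covered) == 24L)
  c(insufficient_wear = wear_h < 72,
    diurnal_gap = !all(hours_covered),
    implausible_acceleration = mean_acceleration_mg > 100,
    poor_calibration = FALSE)
}

#' Hour-of-day wear coverage
#' @param series a [minute_series()].
#' @return logical vector of length 24 (hour has any worn minute).
#' @export
hour_coverage <- function(series) {
  vapply(0:23, function(h)
    any(series$worn[, h * 60 + 1:60, drop = FALSE]), logical(1))
}

#' Daily summary of a minute series
#'
#' Imputes nonwear and computes the daily summary metrics plus QC flags.
#'
#' @param series a [minute_series()] (pre-imputation).
#' @param mean_acceleration_mg mean gravity-removed vector magnitude of the
#'   recording in mg (for the acceleration QC flag); `NA` skips that flag.
#' @return an object of class `daily_summary`: daily step totals, median
#'   daily steps, peak 1-min cadence, wear hours and QC flags.
#' @export
daily_summary <- function(series, mean_acceleration_mg = NA_real_) {
  imp <- impute_nonwear(series)
  flags <- qc_checks(wear_hours(series), hour_coverage(series),
                     if (is.na(mean_acceleration_mg)) 0 else mean_acceleration_mg)
  structure(list(
    daily_steps = rowSums(imp$counts),
    median_daily_steps = median_daily_steps(imp),
    peak_1min_cadence = peak_1min_cadence(imp),
    wear_hours = wear_hours(series),
    mean_acceleration_mg = mean_acceleration_mg,
    qc_flags = flags
  ), class = "daily_summary")
}

#' @export
print.daily_summary <- function(x, ...) {
  cat(sprintf("<daily_summary> %d day(s): median %.0f steps/day, peak cadence %.1f steps/min\n",
              length(x$daily_steps), x$median_daily_steps, x$peak_1min_cadence))
  cat(sprintf("  wear %.1f h; flags: %s\n", x$wear_hours,
              if (any(x$qc_flags)) paste(names(which(x$qc_flags)), collapse = ", ")
              else "none"))
  invisible(x)
}
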