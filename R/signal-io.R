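# Reading, resampling and epoching of raw triaxial accelerometer recordings.

#' Construct a triaxial accelerometer recording
#'
#' The basic container of the package: a uniformly sampled triaxial
#' acceleration series in gravitational units (g), with its sample rate,
#' start time and participant id.
#'
#' @param samples numeric matrix (or coercible data.frame) with 3 columns
#'   (x, y, z accelerations in g), one row per sample.
#' @param sample_rate_hz positive sampling rate in Hz.
#' @param start_time recording start, in seconds (numeric; treated as seconds
#'   since an arbitrary clock origin such as local midnight -- time zones are
#'   out of scope).
#' @param participant_id character id used for grouping in cross-validation.
#' @return an object of class `accel_recording`.
#' @export
accel_recording <- function(samples, sample_rate_hz, start_time = 0,
                            participant_id = "P01") {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("samples must have exactly 3 columns (x, y, z)")
  if (nrow(samples) < 1L) stop("recording must contain at least one sample")
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be a positive number")
  colnames(samples) <- c("x", "y", "z")
  structure(
    list(samples = samples,
         sample_rate_hz = as.numeric(sample_rate_hz),
         start_time = as.numeric(start_time),
         participant_id = as.character(participant_id)),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %s: %d samples @ %.6g Hz (%.1f s)\n",
              x$participant_id, nrow(x$samples), x$sample_rate_hz,
              duration_s(x)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an `accel_recording`.
#' @return numeric duration (samples / rate).
#' @export
duration_s <- function(recording) {
  nrow(recording$samples) / recording$sample_rate_hz
}

#' Write a recording to a long-form CSV
#'
#' Columns `time,x,y,z`; time in seconds, accelerations in g. This is the
#' dialect [read_recording()] reads and the synthetic fixture writer uses.
#'
#' @param recording an `accel_recording`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_recording <- function(recording, path) {
  n <- nrow(recording$samples)
  dt <- data.table::data.table(
    time = recording$start_time + (seq_len(n) - 1) / recording$sample_rate_hz,
    x = recording$samples[, 1], y = recording$samples[, 2],
    z = recording$samples[, 3]
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a triaxial recording from CSV
#'
#' Accepts a long-form CSV with one row per sample. If a time column is
#' present, the sample rate is inferred as `1 / median(diff(time))`; a
#' declared `sample_rate_hz` wins over the inferred rate (with a warning when
#' they disagree by more than 1%). Without a time column the rate must be
#' declared and timestamps are synthesised on a uniform grid.
#'
#' @param path CSV file path.
#' @param time_col,x_col,y_col,z_col column names; set `time_col = NULL` for
#'   files without timestamps.
#' @param sample_rate_hz optional declared sampling rate in Hz.
#' @param participant_id id stored in the recording; defaults to the file
#'   name without extension.
#' @return an `accel_recording`.
#' @export
read_recording <- function(path, time_col = "time", x_col = "x", y_col = "y",
                           z_col = "z", sample_rate_hz = NULL,
                           participant_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c(x_col, y_col, z_col)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("format error: missing columns: ", paste(missing_cols, collapse = ", "))
  samples <- as.matrix(dt[, need, with = FALSE])

  start_time <- 0
  if (!is.null(time_col) && time_col %in% names(dt)) {
    tv <- as.numeric(dt[[time_col]])
    if (length(tv) > 1L && any(diff(tv) <= 0))
      stop("data error: timestamps are not strictly increasing")
    start_time <- tv[1]
    inferred <- if (length(tv) > 1L) 1 / stats::median(diff(tv)) else NA_real_
    if (is.null(sample_rate_hz)) {
      if (!is.finite(inferred))
        stop("cannot infer sample rate from a single sample; declare sample_rate_hz")
      sample_rate_hz <- inferred
    } else if (is.finite(inferred) &&
               abs(inferred - sample_rate_hz) / sample_rate_hz > 0.01) {
      warning(sprintf(
        "declared rate %.6g Hz differs from inferred %.6g Hz; using declared",
        sample_rate_hz, inferred))
    }
  } else if (is.null(sample_rate_hz)) {
    stop("format error: no time column and no declared sample_rate_hz")
  }

  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  accel_recording(samples, sample_rate_hz, start_time, participant_id)
}

#' Resample a recording to a target rate
#'
#' Per-axis linear interpolation onto a uniform grid spanning the original
#' duration. A recording already at the target rate is returned unchanged.
#'
#' @param recording an `accel_recording`.
#' @param target_hz positive target sampling rate in Hz.
#' @return an `accel_recording` at `target_hz`.
#' @export
resample_recording <- function(recording, target_hz) {
  stopifnot(is.numeric(target_hz), length(target_hz) == 1L, target_hz > 0)
  fs <- recording$sample_rate_hz
  if (isTRUE(all.equal(fs, target_hz))) return(recording)
  n <- nrow(recording$samples)
  if (n < 2L) stop("data error: cannot resample a recording with < 2 samples")
  t_old <- (seq_len(n) - 1) / fs
  n_new <- max(1L, round(n * target_hz / fs))
  t_new <- (seq_len(n_new) - 1) / target_hz
  out <- vapply(1:3, function(j) {
    stats::approx(t_old, recording$samples[, j], xout = t_new, rule = 2)$y
  }, numeric(n_new))
  accel_recording(out, target_hz, recording$start_time, recording$participant_id)
}

#' Construct an epoch set
#'
#' Contiguous, non-overlapping fixed-length windows of triaxial samples; the
#' classifier's unit of work. Usually produced by [epoch_split()].
#'
#' @param samples 3-D array `[n_epochs, samples_per_epoch, 3]`.
#' @param sample_rate_hz sampling rate in Hz.
#' @param epoch_length_s epoch length in seconds.
#' @param group_ids participant id per epoch.
#' @param start_s epoch start offset (s) relative to its recording start.
#' @param labels optional walk/nonwalk factor per epoch.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(samples, sample_rate_hz, epoch_length_s, group_ids,
                      start_s, labels = NULL) {
  stopifnot(length(dim(samples)) == 3L, dim(samples)[3] == 3L)
  n <- dim(samples)[1]
  stopifnot(length(group_ids) == n, length(start_s) == n)
  if (!is.null(labels)) {
    labels <- as_walk_label(labels)
    stopifnot(length(labels) == n)
  }
  expected <- round(epoch_length_s * sample_rate_hz)
  if (n > 0L && dim(samples)[2] != expected)
    stop(sprintf("each epoch must have round(epoch_length_s * rate) = %d samples", expected))
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         epoch_length_s = epoch_length_s,
         group_ids = as.character(group_ids),
         start_s = as.numeric(start_s), labels = labels),
    class = "epoch_set"
  )
}

#' Number of epochs in an epoch set
#' @param epochs an `epoch_set`.
#' @return integer count.
#' @export
n_epochs <- function(epochs) dim(epochs$samples)[1]

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %.6g s @ %.6g Hz, %d participant(s)%s\n",
              n_epochs(x), x$epoch_length_s, x$sample_rate_hz,
              length(unique(x$group_ids)),
              if (is.null(x$labels)) "" else
                sprintf(", %d walk", sum(x$labels == "walk"))))
  invisible(x)
}

#' Split a recording into fixed-length epochs
#'
#' Cuts the recording into contiguous non-overlapping windows of
#' `epoch_length_s` seconds (default 10 s, the unit of walk classification).
#' A trailing partial window is discarded.
#'
#' @param recording an `accel_recording`.
#' @param epoch_length_s epoch length in seconds.
#' @return an `epoch_set` (empty, with a warning, if the recording is shorter
#'   than one epoch).
#' @export
epoch_split <- function(recording, epoch_length_s = 10) {
  fs <- recording$sample_rate_hz
  n_per <- round(epoch_length_s * fs)
  if (n_per < 1L) stop("epoch_length_s * sample_rate_hz must be >= 1")
  n <- nrow(recording$samples)
  n_ep <- n %/% n_per
  if (n_ep == 0L) {
    warning("recording shorter than one epoch; returning empty epoch set")
    return(epoch_set(array(0, c(0L, n_per, 3L)), fs, epoch_length_s,
                     character(0), numeric(0)))
  }
  used <- n_ep * n_per
  arr <- array(0, c(n_ep, n_per, 3L))
  for (j in 1:3) arr[, , j] <- t(matrix(recording$samples[seq_len(used), j],
                                        nrow = n_per))
  epoch_set(arr, fs, epoch_length_s,
            group_ids = rep(recording$participant_id, n_ep),
            start_s = (seq_len(n_ep) - 1) * n_per / fs)
}

#' Combine epoch sets from several recordings
#'
#' @param sets a list of `epoch_set` objects with identical sample rate and
#'   epoch length.
#' @return a single pooled `epoch_set`.
#' @export
combine_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  fs <- sets[[1]]$sample_rate_hz
  len <- sets[[1]]$epoch_length_s
  for (s in sets) {
    if (!isTRUE(all.equal(s$sample_rate_hz, fs)) ||
        !isTRUE(all.equal(s$epoch_length_s, len)))
      stop("all epoch sets must share sample rate and epoch length")
  }
  ns <- vapply(sets, n_epochs, integer(1))
  total <- sum(ns)
  n_per <- dim(sets[[1]]$samples)[2]
  arr <- array(0, c(total, n_per, 3L))
  at <- 0L
  for (s in sets) {
    if (n_epochs(s) > 0L) arr[at + seq_len(n_epochs(s)), , ] <- s$samples
    at <- at + n_epochs(s)
  }
  labels <- NULL
  if (all(vapply(sets, function(s) !is.null(s$labels) || n_epochs(s) == 0L,
                 logical(1))))
    labels <- as_walk_label(unlist(lapply(sets, function(s)
      as.character(s$labels))))
  epoch_set(arr, fs, len,
            group_ids = unlist(lapply(sets, `[[`, "group_ids")),
            start_s = unlist(lapply(sets, `[[`, "start_s")),
            labels = labels)
}

#' Subset an epoch set
#' @param epochs an `epoch_set`.
#' @param idx integer or logical index over epochs.
#' @return the subset `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$samples[idx, , , drop = FALSE], epochs$sample_rate_hz,
            epochs$epoch_length_s, epochs$group_ids[idx], epochs$start_s[idx],
            labels = if (!is.null(epochs$labels)) epochs$labels[idx])
}
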