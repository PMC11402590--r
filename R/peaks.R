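# Step detection: local-peak search on the conditioned vector-magnitude
# signal with prominence / width / distance heuristics, gated by the
# predicted walking labels, plus grid-search tuning of the heuristics.

#' Peak-detection heuristics
#'
#' The three tunable heuristics of step detection: minimum topographic
#' prominence (g), minimum time between retained peaks (s), and a bound on
#' peak width at half prominence (s). The tuning grid spans prominence 0.1-1
#' g, distance 0.2-2 s, width 0.01-1 s; values outside those ranges are
#' allowed for free use but warn.
#'
#' @param prominence_g minimum peak prominence in g.
#' @param distance_s minimum spacing between retained peaks in seconds.
#' @param width_s bound on the peak width at half prominence, in seconds.
#' @param width_mode `"max"` (default) treats `width_s` as a maximum width,
#'   `"min"` as a minimum.
#' @return an object of class `detector_params`.
#' @export
detector_params <- function(prominence_g, distance_s, width_s,
                            width_mode = c("max", "min")) {
  width_mode <- match.arg(width_mode)
  stopifnot(prominence_g > 0, distance_s > 0, width_s > 0)
  if (prominence_g < 0.1 || prominence_g > 1 ||
      distance_s < 0.2 || distance_s > 2 ||
      width_s < 0.01 || width_s > 1)
    warning("detector parameters outside the standard tuning ranges ",
            "(prominence 0.1-1 g, distance 0.2-2 s, width 0.01-1 s)")
  structure(list(prominence_g = prominence_g, distance_s = distance_s,
                 width_s = width_s, width_mode = width_mode),
            class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf("<detector_params> prominence %.3g g, distance %.3g s, width %s %.3g s\n",
              x$prominence_g, x$distance_s,
              if (x$width_mode == "max") "<=" else ">=", x$width_s))
  invisible(x)
}

# All strict local maxima of v with their topographic prominence and width at
# half prominence (in samples). Candidates are independent of the detector
# parameters, so tuning can compute them once per signal and re-filter.
peak_candidates <- function(v, sample_rate_hz) {
  n <- length(v)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width_s = numeric(0))
  if (n < 3L) return(empty)
  d <- diff(v)
  idx <- which(d[-(n - 1L)] > 0 & d[-1L] < 0) + 1L
  if (!length(idx)) return(empty)
  prom <- numeric(length(idx))
  width <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    higher_l <- which(v[seq_len(i - 1L)] > v[i])
    lb <- if (length(higher_l)) max(higher_l) else 0L
    left_min <- min(v[(lb + 1L):i])
    higher_r <- which(v[(i + 1L):n] > v[i])
    rb <- if (length(higher_r)) i + min(higher_r) else n + 1L
    right_min <- min(v[i:(rb - 1L)])
    prom[k] <- v[i] - max(left_min, right_min)
    # width at half prominence: interpolated crossings of the reference
    # height on each side, bounded by the peak's base segments.
    ref <- v[i] - prom[k] / 2
    j <- i
    while (j > lb + 1L && v[j] > ref) j <- j - 1L
    xl <- j
    if (v[j] < ref) xl <- j + (ref - v[j]) / (v[j + 1L] - v[j])
    j <- i
    while (j < rb - 1L && v[j] > ref) j <- j + 1L
    xr <- j
    if (v[j] < ref) xr <- j - (ref - v[j]) / (v[j - 1L] - v[j])
    width[k] <- (xr - xl) / sample_rate_hz
  }
  data.frame(index = idx, height = v[idx], prominence = prom, width_s = width)
}

# Greedy distance suppression: process candidates by descending height
# (ties: lower index first); keep a peak iff it is >= d_samples away from
# every already-kept peak. Returns sorted kept indices.
suppress_by_distance <- function(index, height, d_samples) {
  if (!length(index)) return(integer(0))
  ord <- order(-height, index)
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) || all(abs(index[k] - kept) >= d_samples))
      kept <- c(kept, index[k])
  }
  sort(kept)
}

#' Find step-like peaks in a 1-D signal
#'
#' Strict local maxima whose topographic prominence is at least
#' `prominence_g`, whose width at half prominence satisfies the width bound,
#' thinned so retained peaks are at least `distance_s` apart. When two peaks
#' are closer than the distance, the higher one wins (greedy suppression by
#' descending height).
#'
#' @param v numeric signal (typically a conditioned vector magnitude, in g).
#' @param sample_rate_hz sampling rate in Hz.
#' @param params a [detector_params()] object.
#' @return integer vector of peak sample indices (1-based, sorted).
#' @export
find_peaks_1d <- function(v, sample_rate_hz, params) {
  stopifnot(inherits(params, "detector_params"))
  cand <- peak_candidates(v, sample_rate_hz)
  keep <- cand$prominence >= params$prominence_g
  keep <- keep & if (params$width_mode == "max")
    cand$width_s <= params$width_s else cand$width_s >= params$width_s
  cand <- cand[keep, , drop = FALSE]
  suppress_by_distance(cand$index, cand$height,
                       params$distance_s * sample_rate_hz)
}

#' Step events
#'
#' Ordered step timestamps (seconds relative to the recording start) with the
#' index of the 10-s epoch each step falls in.
#'
#' @param time_s strictly increasing numeric step times (s).
#' @param epoch_index integer epoch index per step.
#' @return an object of class `step_events`.
#' @export
step_events <- function(time_s, epoch_index = rep(NA_integer_, length(time_s))) {
  stopifnot(length(time_s) == length(epoch_index))
  if (length(time_s) > 1L && any(diff(time_s) <= 0))
    stop("step times must be strictly increasing")
  structure(data.frame(time_s = as.numeric(time_s),
                       epoch_index = as.integer(epoch_index)),
            class = c("step_events", "data.frame"))
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> %d steps%s\n", nrow(x),
              if (nrow(x)) sprintf(" spanning %.1f-%.1f s", min(x$time_s),
                                   max(x$time_s)) else ""))
  invisible(x)
}

#' Detect steps in a recording gated by walking labels
#'
#' Runs peak detection on the conditioned vector magnitude of each maximal
#' run of consecutive walking epochs. Runs are processed as concatenated
#' signals (so steps at epoch boundaries are not lost); set
#' `per_epoch = TRUE` to count within each 10-s epoch independently.
#' Non-walking spans contribute zero steps.
#'
#' @param recording an `accel_recording`.
#' @param walk_labels per-epoch labels (factor/character `walk`/`nonwalk` or
#'   logical), aligned to `epoch_split(recording, epoch_length_s)`.
#' @param params a [detector_params()] object.
#' @param epoch_length_s epoch length in seconds (default 10).
#' @param per_epoch detect within each epoch separately instead of within
#'   concatenated walking runs.
#' @return a [step_events()] object.
#' @export
detect_steps <- function(recording, walk_labels, params, epoch_length_s = 10,
                         per_epoch = FALSE) {
  fs <- recording$sample_rate_hz
  n_per <- round(epoch_length_s * fs)
  n_ep <- nrow(recording$samples) %/% n_per
  labels <- as_walk_label(walk_labels)
  if (length(labels) != n_ep)
    stop(sprintf("data error: %d labels do not align with %d epochs",
                 length(labels), n_ep))
  times <- numeric(0)
  runs <- label_runs(labels == "walk")
  runs <- runs[runs$value, , drop = FALSE]
  for (r in seq_len(nrow(runs))) {
    blocks <- if (per_epoch) runs$start[r]:runs$end[r] else runs$start[r]
    ends <- if (per_epoch) blocks else runs$end[r]
    for (b in seq_along(blocks)) {
      s0 <- (blocks[b] - 1L) * n_per + 1L
      s1 <- ends[b] * n_per
      vm <- conditioned_vm(recording$samples[s0:s1, , drop = FALSE], fs)
      idx <- find_peaks_1d(vm, fs, params)
      times <- c(times, (s0 - 1L + idx - 1L) / fs)
    }
  }
  times <- sort(times)
  step_events(times, epoch_index = as.integer(times %/% epoch_length_s) + 1L)
}

#' Default tuning grid for the detector heuristics
#'
#' Prominence 0.1-1 g in steps of 0.1, distance 0.2-2 s in steps of 0.2, and
#' width 10 ms plus 0.1-1 s in steps of 0.1 (1100 cells).
#'
#' @return a data.frame with columns `prominence_g`, `distance_s`, `width_s`.
#' @export
default_detector_grid <- function() {
  expand.grid(prominence_g = seq(0.1, 1, by = 0.1),
              distance_s = seq(0.2, 2, by = 0.2),
              width_s = c(0.01, seq(0.1, 1, by = 0.1)),
              KEEP.OUT.ATTRS = FALSE)
}

#' Tune the detector heuristics by exhaustive grid search
#'
#' Evaluates every grid cell on a validation set of (conditioned VM signal,
#' true step count) pairs and returns the cell minimising the mean absolute
#' error of per-item step counts. Ties are broken toward the most
#' conservative cell: larger prominence, then larger distance, then larger
#' width.
#'
#' @param validation a list of items, each a list with elements `vm` (numeric
#'   conditioned VM signal), `sample_rate_hz`, and `true_count`.
#' @param grid data.frame of candidate parameters (see
#'   [default_detector_grid()]).
#' @param width_mode passed to [detector_params()].
#' @return the selected [detector_params()], with the achieved MAE in
#'   attribute `"mae"` and the full per-cell MAE vector in attribute
#'   `"grid_mae"`.
#' @export
tune_detector <- function(validation, grid = default_detector_grid(),
                          width_mode = "max") {
  if (!length(validation)) stop("parameter error: empty validation set")
  if (!nrow(grid)) stop("parameter error: empty grid")
  cands <- lapply(validation, function(item)
    c(peak_candidates(item$vm, item$sample_rate_hz),
      list(fs = item$sample_rate_hz, true_count = item$true_count)))
  mae <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- vapply(cands, function(cc) {
      keep <- cc$prominence >= grid$prominence_g[g]
      keep <- keep & if (width_mode == "max")
        cc$width_s <= grid$width_s[g] else cc$width_s >= grid$width_s[g]
      cnt <- length(suppress_by_distance(cc$index[keep], cc$height[keep],
                                         grid$distance_s[g] * cc$fs))
      abs(cnt - cc$true_count)
    }, numeric(1))
    mae[g] <- mean(errs)
  }
  best <- which(mae == min(mae))
  if (length(best) > 1L) {
    ord <- order(-grid$prominence_g[best], -grid$distance_s[best],
                 -grid$width_s[best])
    best <- best[ord[1]]
  }
  out <- detector_params(grid$prominence_g[best], grid$distance_s[best],
                         grid$width_s[best], width_mode = width_mode)
  attr(out, "mae") <- mae[best]
  attr(out, "grid_mae") <- mae
  out
}
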