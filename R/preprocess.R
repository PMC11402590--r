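# Conditioning of the triaxial signal into the 1-D vector magnitude used for
# peak detection: Euclidean norm minus 1 g, clipped to +/-2 g, low-pass
# filtered (4th-order Butterworth, 5 Hz, zero phase).

#' Gravity-removed vector magnitude
#'
#' `sqrt(x^2 + y^2 + z^2) - 1`, in g. Subtracting 1 g removes the static
#' gravity component regardless of device orientation, making the result
#' invariant to any rotation of the sensor frame.
#'
#' @param samples numeric matrix with 3 columns (g).
#' @return numeric vector, one value per sample (g).
#' @export
vector_magnitude <- function(samples) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == 3L)
  sqrt(rowSums(samples^2)) - 1
}

#' Clip a signal to a symmetric bound
#'
#' @param v numeric vector (g).
#' @param bound positive clip bound; values are limited to `[-bound, bound]`.
#'   Default 2 g.
#' @return clipped numeric vector.
#' @export
clip_signal <- function(v, bound = 2) {
  stopifnot(bound > 0)
  pmin(pmax(v, -bound), bound)
}

# One pass of the IIR difference equation y = (b, a) * x with zero initial
# conditions, via stats::filter (convolution for the numerator, recursive for
# the denominator) -- O(n) in C.
iir_pass <- function(b, a, x) {
  nb <- length(b)
  xb <- stats::filter(c(rep(0, nb - 1), x), filter = b, method = "convolution",
                      sides = 1)
  xb <- as.numeric(xb)[-seq_len(nb - 1)]
  if (length(a) > 1L)
    as.numeric(stats::filter(xb, filter = -a[-1], method = "recursive"))
  else xb
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-`order` low-pass Butterworth filter forward and backward
#' (zero phase, so peak times are not shifted -- step timestamps feed
#' minute-level cadence downstream). The signal is extended at both ends by
#' odd reflection before filtering to suppress edge transients; the output
#' has the same length as the input.
#'
#' @param v numeric signal.
#' @param sample_rate_hz sampling rate in Hz.
#' @param cutoff_hz low-pass cutoff in Hz (default 5); must be below the
#'   Nyquist rate.
#' @param order filter order (default 4).
#' @return filtered numeric vector, same length as `v`.
#' @export
butterworth_lowpass <- function(v, sample_rate_hz, cutoff_hz = 5, order = 4) {
  stopifnot(sample_rate_hz > 0)
  if (!(cutoff_hz > 0 && cutoff_hz < sample_rate_hz / 2))
    stop("parameter error: cutoff_hz must lie in (0, sample_rate_hz / 2)")
  n <- length(v)
  if (n < 2L) return(v)
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), type = "low")
  b <- as.numeric(bf$b); a <- as.numeric(bf$a)
  # Odd-reflection pad long enough for the slowest filter pole to decay to
  # numerical noise (the slowest order-4 Butterworth pole decays like
  # exp(-sin(pi/8) * 2*pi*cutoff * t)).
  p <- min(n - 1L, as.integer(ceiling(3 * order * sample_rate_hz / cutoff_hz)))
  if (p > 0L) {
    pre <- 2 * v[1] - v[seq(p + 1L, 2L)]
    post <- 2 * v[n] - v[seq(n - 1L, n - p)]
    xx <- c(pre, v, post)
  } else xx <- v
  y <- iir_pass(b, a, xx)
  y <- rev(iir_pass(b, a, rev(y)))
  y[p + seq_len(n)]
}

#' Conditioned vector-magnitude signal
#'
#' The 1-D input of step detection: gravity-removed vector magnitude, clipped
#' to +/- `clip_g`, then zero-phase low-pass filtered. The operations are
#' applied in that order (clip before filter).
#'
#' @param x an `accel_recording`, or a numeric matrix of triaxial samples.
#' @param sample_rate_hz sampling rate in Hz (ignored when `x` is a
#'   recording).
#' @param clip_g symmetric clip bound in g (default 2).
#' @param cutoff_hz,order Butterworth low-pass parameters (defaults 5 Hz,
#'   order 4).
#' @return numeric vector (g), one value per sample.
#' @export
conditioned_vm <- function(x, sample_rate_hz = NULL, clip_g = 2, cutoff_hz = 5,
                           order = 4) {
  if (inherits(x, "accel_recording")) {
    sample_rate_hz <- x$sample_rate_hz
    x <- x$samples
  }
  if (is.null(sample_rate_hz))
    stop("sample_rate_hz is required when x is a raw sample matrix")
  v <- clip_signal(vector_magnitude(x), bound = clip_g)
  butterworth_lowpass(v, sample_rate_hz, cutoff_hz = cutoff_hz, order = order)
}
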