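#' Uniformly sampled single-channel signal
#'
#' Container for a 1-D time series sampled at a fixed rate, the working
#' representation of a blood volume pulse (BVP) signal throughout the package.
#'
#' @param values Numeric vector of sample values (arbitrary units).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `sampled_signal`: a list with elements
#'   `values`, `fs` and `t0`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * (0:99) / 25), fs = 25)
#' signal_times(s)[1:4]
#' @export
sampled_signal <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  .check_scalar(fs, "fs", positive = TRUE)
  .check_scalar(t0, "t0")
  if (length(values) < 1L) stop("signal must contain at least one sample")
  .check_finite(values, "values")
  structure(list(values = values, fs = fs, t0 = t0), class = "sampled_signal")
}

#' Three-channel color trace
#'
#' Container for a uniformly sampled T x 3 matrix of spatially averaged
#' color values in R, G, B channel order -- the input of [extract_bvp()].
#'
#' @param values Numeric T x 3 matrix (columns R, G, B).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `rgb_trace`.
#' @export
rgb_trace <- function(values, fs, t0 = 0) {
  values <- as.matrix(values)
  if (ncol(values) != 3L) stop("trace must have exactly 3 channels, got ", ncol(values))
  if (nrow(values) < 2L) stop("trace must have at least 2 samples")
  .check_scalar(fs, "fs", positive = TRUE)
  .check_scalar(t0, "t0")
  .check_finite(values, "values")
  colnames(values) <- c("r", "g", "b")
  structure(list(values = values, fs = fs, t0 = t0), class = "rgb_trace")
}

#' Series of systolic peak times
#'
#' @param times Strictly increasing peak times in seconds (may be empty).
#' @param indices Optional integer sample indices of the peaks.
#' @param source Which detector produced the peaks: one of `"two_window"`,
#'   `"ssf"`, `"local_max"`, `"ground_truth"`.
#' @return An object of class `peak_series`.
#' @export
peak_series <- function(times, indices = NULL,
                        source = c("ground_truth", "two_window", "ssf", "local_max")) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (length(times) > 0) {
    .check_finite(times, "times")
    if (any(diff(times) <= 0)) stop("peak times must be strictly increasing")
  }
  if (!is.null(indices)) {
    indices <- as.integer(indices)
    if (length(indices) != length(times)) stop("indices and times differ in length")
  }
  structure(list(times = times, indices = indices, source = source),
            class = "peak_series")
}

#' Sample times of a signal or trace
#'
#' @param x A `sampled_signal` or `rgb_trace`.
#' @return Numeric vector `t0 + (0:(n-1))/fs`.
#' @export
signal_times <- function(x) {
  n <- if (is.matrix(x$values)) nrow(x$values) else length(x$values)
  x$t0 + (seq_len(n) - 1) / x$fs
}

#' Number of samples
#' @param x A `sampled_signal` or `rgb_trace`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  if (is.matrix(x$values)) nrow(x$values) else length(x$values)
}

#' Record duration in seconds
#' @param x A `sampled_signal`, `rgb_trace` or `prv_series`.
#' @return Duration `(n - 1)/fs` in seconds.
#' @export
signal_duration <- function(x) (n_samples(x) - 1) / x$fs

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %.6g Hz, t0 = %.3f s (%.1f s)\n",
              length(x$values), x$fs, x$t0, signal_duration(x)))
  invisible(x)
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace> %d samples x 3 channels @ %.6g Hz, t0 = %.3f s (%.1f s)\n",
              nrow(x$values), x$fs, x$t0, signal_duration(x)))
  invisible(x)
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("<peak_series> %d peaks, source = %s\n", length(x$times), x$source))
  invisible(x)
}

## ---- internal validators ----

.check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop(name, " must be > 0")
  invisible(x)
}

.check_finite <- function(x, name) {
  bad <- which(!is.finite(x))
  if (length(bad) > 0)
    stop("non-finite ", name, " at index ", bad[1])
  invisible(x)
}
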