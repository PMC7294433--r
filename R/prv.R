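#' Inter-beat intervals from a peak series
#'
#' @param peaks A `peak_series` with at least 2 peaks.
#' @return List of class `ibi_series` with `intervals` (successive peak
#'   time differences, seconds) and `anchor_times` (the later peak of each
#'   pair).
#' @examples
#' ibi_from_peaks(peak_series(c(1, 2, 3)))$intervals
#' @export
ibi_from_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_series"))
  t <- peaks$times
  if (length(t) < 2) stop("need at least 2 peaks to form inter-beat intervals")
  if (any(diff(t) <= 0)) stop("peak times must be strictly increasing")
  structure(list(intervals = diff(t), anchor_times = t[-1]),
            class = "ibi_series")
}

#' Interpolate inter-beat intervals to a uniform PRV series
#'
#' Turns the irregular event series of inter-beat intervals into a
#' uniformly sampled pulse-rate-variability signal by interpolating the
#' interval values (anchored at the later peak of each pair) onto a grid at
#' `fs_out` (default 200 Hz), the standard discrete-event-series step for
#' spectral PRV analysis. The interpolant passes exactly through the anchor
#' points.
#'
#' @param ibi An `ibi_series`.
#' @param fs_out Output grid rate in Hz (default 200).
#' @param method `"cubic_spline"` (natural cubic spline, default) or
#'   `"linear"`. Fewer than 4 intervals fall back to linear (with a
#'   message); fewer than 2 is an error.
#' @return List of class `prv_series` with `times`, `values` (seconds) and
#'   `fs_out`.
#' @export
interpolate_prv <- function(ibi, fs_out = 200, method = c("cubic_spline", "linear")) {
  stopifnot(inherits(ibi, "ibi_series"))
  method <- match.arg(method)
  .check_scalar(fs_out, "fs_out", positive = TRUE)
  at <- ibi$anchor_times
  iv <- ibi$intervals
  if (length(iv) < 2) stop("need at least 2 intervals to interpolate")
  if (method == "cubic_spline" && length(iv) < 4) {
    message("fewer than 4 intervals: falling back to linear interpolation")
    method <- "linear"
  }
  k <- 0:floor((at[length(at)] - at[1]) * fs_out + 1e-9)
  grid <- at[1] + k / fs_out
  f <- .prv_interpolant(at, iv, method)
  structure(list(times = grid, values = f(grid), fs_out = fs_out,
                 method = method),
            class = "prv_series")
}

.prv_interpolant <- function(anchor_times, intervals, method) {
  if (method == "cubic_spline") {
    splinefun(anchor_times, intervals, method = "natural")
  } else {
    f <- stats::approxfun(anchor_times, intervals, rule = 2)
    function(t) f(t)
  }
}

#' Root mean square of successive inter-beat interval differences
#'
#' `RMSSD = sqrt( (1/(N-1)) * sum_{i=1}^{N-1} (IBI(i+1) - IBI(i))^2 )`,
#' the standard short-term variability statistic.
#'
#' @param ibi An `ibi_series` or a numeric vector of intervals (seconds),
#'   length >= 2.
#' @return RMSSD in seconds.
#' @examples
#' rmssd(c(0.8, 1.0, 0.8)) # 0.2
#' @export
rmssd <- function(ibi) {
  iv <- .interval_vec(ibi)
  sqrt(mean(diff(iv)^2))
}

#' Standard deviation of the inter-beat interval series
#'
#' Sample standard deviation (n - 1 denominator) of the intervals, the
#' SDNN-style dispersion statistic.
#'
#' @inheritParams rmssd
#' @return Standard deviation in seconds.
#' @export
std_ibi <- function(ibi) {
  iv <- .interval_vec(ibi)
  sd(iv)
}

.interval_vec <- function(ibi) {
  iv <- if (inherits(ibi, "ibi_series")) ibi$intervals else as.numeric(ibi)
  if (length(iv) < 2) stop("need at least 2 intervals")
  .check_finite(iv, "intervals")
  iv
}

#' LF and HF band powers of a PRV series
#'
#' Welch power spectral density of the mean-removed PRV series (Hann
#' window, 50% overlap, segment length `min(duration/2, 60)` seconds),
#' integrated over the conventional low-frequency (0.04-0.15 Hz) and
#' high-frequency (0.15-0.4 Hz) bands by the trapezoid rule.
#'
#' @param prv A `prv_series` of duration >= 10 s.
#' @param lf_band,hf_band Band limits in Hz.
#' @return List with `lf_power`, `hf_power` (s^2), `lf_hf_ratio`
#'   (NA with `hf_zero = TRUE` when the HF power is zero).
#' @export
psd_bands <- function(prv, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)) {
  stopifnot(inherits(prv, "prv_series"))
  dur <- (length(prv$values) - 1) / prv$fs_out
  if (dur < 10)
    stop(sprintf("PRV series too short for band powers: %.2f s < 10 s", dur))
  seg_s <- min(dur / 2, 60)
  psd <- welch_psd(prv$values, fs = prv$fs_out, seg_len = round(seg_s * prv$fs_out))
  lf <- .band_power(psd, lf_band)
  hf <- .band_power(psd, hf_band)
  hf_zero <- hf <= 0
  list(lf_power = lf, hf_power = hf,
       lf_hf_ratio = if (hf_zero) NA_real_ else lf / hf,
       hf_zero = hf_zero)
}

#' Welch power spectral density estimate
#'
#' Mean of modified periodograms over Hann-windowed, 50%-overlapping
#' segments of the mean-removed signal; one-sided density normalized so
#' that the integral over frequency approximates the signal variance.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in samples (capped at `length(x)`).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  x <- as.numeric(x) - mean(x)
  n <- length(x)
  seg_len <- min(as.integer(seg_len), n)
  if (seg_len < 8) stop("Welch segment too short")
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  acc <- numeric(seg_len)
  for (s in starts) {
    X <- fft(x[s:(s + seg_len - 1L)] * win)
    acc <- acc + Mod(X)^2
  }
  scale <- fs * sum(win^2) * length(starts)
  p <- acc / scale
  half <- seq_len(floor(seg_len / 2) + 1L)
  psd <- p[half]
  interior <- 2:(length(half) - if (seg_len %% 2L == 0L) 1L else 0L)
  psd[interior] <- 2 * psd[interior]
  list(freq = (half - 1) * fs / seg_len, psd = psd)
}

.band_power <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  f <- psd$freq[sel]
  p <- psd$psd[sel]
  if (length(f) < 2) return(0)
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Time and frequency domain PRV features
#'
#' Convenience wrapper computing the feature set used throughout the
#' evaluation: interval standard deviation, RMSSD, and (when the record is
#' long enough for a meaningful spectrum) LF/HF band powers of the
#' interpolated PRV series.
#'
#' @param peaks A `peak_series` (or an `ibi_series`).
#' @param fs_out PRV interpolation rate in Hz (default 200).
#' @param method Interpolation method, see [interpolate_prv()].
#' @return List of class `prv_features`: `std_ibi`, `rmssd`, `lf_power`,
#'   `hf_power`, `lf_hf_ratio` (spectral fields are `NA` for records whose
#'   PRV support is under 10 s).
#' @export
prv_features <- function(peaks, fs_out = 200, method = "cubic_spline") {
  ibi <- if (inherits(peaks, "ibi_series")) peaks else ibi_from_peaks(peaks)
  out <- list(std_ibi = std_ibi(ibi), rmssd = rmssd(ibi),
              lf_power = NA_real_, hf_power = NA_real_, lf_hf_ratio = NA_real_)
  span <- ibi$anchor_times[length(ibi$anchor_times)] - ibi$anchor_times[1]
  if (span >= 10 && length(ibi$intervals) >= 2) {
    prv <- interpolate_prv(ibi, fs_out = fs_out, method = method)
    bands <- psd_bands(prv)
    out$lf_power <- bands$lf_power
    out$hf_power <- bands$hf_power
    out$lf_hf_ratio <- bands$lf_hf_ratio
  }
  structure(out, class = "prv_features")
}

#' @export
print.prv_features <- function(x, ...) {
  cat(sprintf("<prv_features> std_ibi = %.4f s, rmssd = %.4f s, LF = %.3g, HF = %.3g, LF/HF = %.3g\n",
              x$std_ibi, x$rmssd, x$lf_power, x$hf_power, x$lf_hf_ratio))
  invisible(x)
}
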