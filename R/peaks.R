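#' Per-sample beat window length from a sliding FFT
#'
#' Estimates the instantaneous beat period for the adaptive two-window
#' detector: for every sample, the dominant frequency `Fb(i)` inside the
#' heart-rate band is taken from the magnitude spectrum of a Hann-windowed
#' segment (default 10 s) centered on the sample, zero-padded x4 for finer
#' frequency resolution; the beat window is `Wb(i) = 1/Fb(i)` seconds.
#' Samples closer than half a window to either record edge reuse the
#' nearest full-window estimate. If the whole record is shorter than the
#' FFT window, a single whole-record estimate is used everywhere.
#'
#' @param bvp A detrended `sampled_signal`.
#' @param hr_band Heart-rate band `c(f_min, f_max)` in Hz.
#' @param fft_window_s Analysis window length in seconds (default 10).
#' @return Numeric vector of per-sample beat window lengths `Wb` (seconds).
#' @export
estimate_beat_window <- function(bvp, hr_band = c(40, 240) / 60, fft_window_s = 10) {
  stopifnot(inherits(bvp, "sampled_signal"))
  v <- bvp$values
  fs <- bvp$fs
  n <- length(v)
  win <- min(n, max(4L, round(fft_window_s * fs)))
  L <- 4L * win
  freqs <- (0:(L - 1)) * fs / L
  band_idx <- which(freqs >= hr_band[1] & freqs <= hr_band[2])
  if (length(band_idx) < 2) stop("FFT window too short to resolve the heart-rate band")
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  starts <- seq_len(n - win + 1L)
  fb <- numeric(length(starts))
  warned <- FALSE
  mid <- sqrt(hr_band[1] * hr_band[2])
  for (k in starts) {
    seg <- v[k:(k + win - 1L)]
    if (all(abs(seg) < .Machine$double.eps * 100)) {
      if (!warned) { warning("all-zero FFT window: using band midpoint frequency"); warned <- TRUE }
      fb[k] <- mid
    } else {
      sp <- Mod(fft(c(seg * hann, numeric(L - win))))[band_idx]
      fb[k] <- freqs[band_idx[which.max(sp)]]
    }
  }
  # map window starts to window centers, clamp edges to nearest full window
  centers <- starts + (win - 1L) / 2
  idx <- pmin(pmax(seq_len(n) - (win - 1L) / 2, 1), length(starts))
  1 / fb[round(idx)]
}

#' Centered moving average with per-sample window
#'
#' Averages over an odd-length window centered on each sample; the window
#' length may vary per sample (as the adaptive beat/peak windows do). At
#' the record edges the window shrinks to the valid index range.
#'
#' @param x A `sampled_signal` or numeric vector.
#' @param window_samples Odd positive integer window length(s) in samples;
#'   a scalar or one value per sample. Even values are rounded up to the
#'   next odd length (with a message).
#' @return Same type as `x`, holding the moving average.
#' @export
moving_average <- function(x, window_samples) {
  v <- if (inherits(x, "sampled_signal")) x$values else as.numeric(x)
  n <- length(v)
  w <- as.integer(rep_len(window_samples, n))
  if (any(w < 1)) stop("window_samples must be >= 1")
  if (any(w %% 2L == 0L)) {
    message("even moving-average window rounded up to next odd length")
    w[w %% 2L == 0L] <- w[w %% 2L == 0L] + 1L
  }
  h <- (w - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  cs <- c(0, cumsum(v))
  ma <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (inherits(x, "sampled_signal")) { x$values <- ma; x } else ma
}

.force_odd <- function(k) {
  k <- as.integer(pmax(1L, round(k)))
  k + (1L - k %% 2L)
}

#' Adaptive two-window systolic peak detection
#'
#' Event-based detector built on two moving averages: a beat-period average
#' `MAb` (window `Wb(i)`, estimated per sample by [estimate_beat_window()])
#' and a systolic-peak-period average `MAp` (window `Wp(i) = 0.25 * Wb(i)`).
#' Maximal runs where `MAp(i) > MAb(i)` (strict) form candidate blocks of
#' interest; blocks narrower than `THR2` -- the mean peak-window length in
#' samples over all in-block samples -- are discarded as noise; each
#' surviving block contributes one peak at the argmax of the signal (ties
#' break to the earliest sample). Both thresholds adapt to the record, so
#' the detector is invariant to positive rescaling of the input.
#'
#' @param bvp A detrended, sign-fixed `sampled_signal`.
#' @param hr_band Heart-rate band in Hz for the beat-window estimate.
#' @param fft_window_s FFT window length in seconds (default 10).
#' @param wp_factor Peak-window fraction of the beat window (default 0.25).
#' @return List with `peaks` (a `peak_series`) and `state` (per-sample
#'   `Wb`, `Wp` in seconds, `MAb`, `MAp`, `THR1 = MAb`, the scalar `THR2`
#'   in samples, a data frame of surviving `blocks`, and diagnostic counts
#'   `n_raw_blocks` / `n_discarded_blocks`).
#' @export
two_window_detect <- function(bvp, hr_band = c(40, 240) / 60,
                              fft_window_s = 10, wp_factor = 0.25) {
  stopifnot(inherits(bvp, "sampled_signal"))
  v <- bvp$values
  fs <- bvp$fs
  n <- length(v)
  Wb_s <- estimate_beat_window(bvp, hr_band, fft_window_s)
  Wp_s <- wp_factor * Wb_s
  Wb_n <- .force_odd(Wb_s * fs)
  Wp_n <- .force_odd(Wp_s * fs)
  MAb <- moving_average(v, Wb_n)
  MAp <- moving_average(v, Wp_n)
  above <- MAp > MAb
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  blocks <- data.frame(start = starts[keep], end = ends[keep])
  n_raw <- nrow(blocks)
  thr2 <- if (n_raw > 0) {
    in_block <- unlist(Map(seq.int, blocks$start, blocks$end), use.names = FALSE)
    mean(Wp_n[in_block])
  } else NA_real_
  peaks_idx <- integer(0)
  n_disc <- 0L
  if (n_raw > 0) {
    widths <- blocks$end - blocks$start + 1L
    surv <- widths >= thr2
    n_disc <- sum(!surv)
    blocks <- blocks[surv, , drop = FALSE]
    peaks_idx <- vapply(seq_len(nrow(blocks)), function(b) {
      i0 <- blocks$start[b]
      i0 + which.max(v[i0:blocks$end[b]]) - 1L
    }, integer(1))
  }
  peaks <- peak_series(bvp$t0 + (peaks_idx - 1) / fs, indices = peaks_idx,
                       source = "two_window")
  state <- list(Wb = Wb_s, Wp = Wp_s, MAb = MAb, MAp = MAp, THR1 = MAb,
                THR2 = thr2,
                blocks = if (n_raw > 0) cbind(blocks, width = blocks$end - blocks$start + 1L)
                         else blocks,
                n_raw_blocks = n_raw, n_discarded_blocks = n_disc)
  list(peaks = peaks, state = state)
}

#' Slope sum function transform
#'
#' Enhances pulse upstrokes by summing the positive sample-to-sample
#' increments over a trailing window:
#' `SSF(i) = sum_{k = i-w+1}^{i} max(y(k) - y(k-1), 0)` for `i > w`
#' (samples), and 0 for `i <= w`. The output is non-negative and exactly
#' zero wherever the trailing window is non-increasing.
#'
#' @param bvp A `sampled_signal`.
#' @param w_ssf Trailing window length in seconds (default 0.4).
#' @return A `sampled_signal` of the same length with class
#'   `c("ssf_signal", "sampled_signal")` and attribute `w_ssf_samples`.
#' @export
ssf_transform <- function(bvp, w_ssf = 0.4) {
  stopifnot(inherits(bvp, "sampled_signal"))
  if (w_ssf <= 0) stop("w_ssf must be > 0")
  v <- bvp$values
  n <- length(v)
  w <- max(1L, round(w_ssf * bvp$fs))
  if (n <= w) stop("signal shorter than the SSF window")
  dy <- c(0, pmax(diff(v), 0))
  out <- numeric(n)
  for (i in (w + 1L):n) out[i] <- sum(dy[(i - w + 1L):i])
  res <- sampled_signal(out, fs = bvp$fs, t0 = bvp$t0)
  attr(res, "w_ssf_samples") <- w
  class(res) <- c("ssf_signal", class(res))
  res
}

#' Slope-sum-function peak detection
#'
#' Detects systolic peaks as strict local maxima of the detrended SSF
#' signal exceeding `height_factor * mean_abs(detrended SSF)`, with a
#' minimum peak separation enforced by keeping the higher of any
#' conflicting pair (iterating from the highest candidate down). Peak
#' times refer to the SSF signal; the transform systematically shifts the
#' waveform shape, so locations are not directly comparable to the raw
#' signal's apexes (interval sequences largely are).
#'
#' @param bvp A `sampled_signal`.
#' @param w_ssf SSF trailing window in seconds (default 0.4).
#' @param height_factor Threshold factor on the detrended SSF amplitude
#'   (default 0.175).
#' @param min_distance Minimum peak separation in seconds (default 0.24).
#' @param detrend_method Detrending applied to the SSF signal before
#'   thresholding.
#' @return A `peak_series` with `source = "ssf"`.
#' @export
ssf_detect <- function(bvp, w_ssf = 0.4, height_factor = 0.175,
                       min_distance = 0.24,
                       detrend_method = c("smoothness_prior", "linear")) {
  detrend_method <- match.arg(detrend_method)
  s <- ssf_transform(bvp, w_ssf)
  sd_sig <- center_detrend(s, method = detrend_method)
  v <- sd_sig$values
  thr <- height_factor * mean_abs(v)
  cand <- .local_maxima(v)
  cand <- cand[v[cand] > thr]
  keep <- .enforce_min_distance(cand, v[cand], min_distance * bvp$fs)
  peak_series(bvp$t0 + (keep - 1) / bvp$fs, indices = keep, source = "ssf")
}

#' Configuration for the rule-based local-maximum detector
#'
#' Thresholds are relative to the mean absolute value of the detrended
#' signal, mirroring the usual `findpeaks`-style rules.
#'
#' @param min_height_factor Minimum peak height as a multiple of
#'   `mean_abs(y)` (default 0.75).
#' @param min_prominence_factor Minimum topographic prominence as a
#'   multiple of `mean_abs(y)` (default 0.3).
#' @param min_distance Minimum peak separation in seconds (default 0.24).
#' @return List of class `local_max_config`.
#' @export
local_max_config <- function(min_height_factor = 0.75,
                             min_prominence_factor = 0.3,
                             min_distance = 0.24) {
  if (min_height_factor < 0 || min_prominence_factor < 0 || min_distance < 0)
    stop("local-max configuration values must be >= 0")
  structure(list(min_height_factor = min_height_factor,
                 min_prominence_factor = min_prominence_factor,
                 min_distance = min_distance),
            class = "local_max_config")
}

#' Rule-based local-maximum peak detection
#'
#' Strict local maxima of the detrended signal, filtered by minimum height
#' (`>= min_height_factor * mean_abs(y)`), minimum topographic prominence
#' (`>= min_prominence_factor * mean_abs(y)`) and minimum separation
#' (higher peak wins conflicts).
#'
#' @param bvp A detrended `sampled_signal`.
#' @param config A [local_max_config()].
#' @return A `peak_series` with `source = "local_max"`.
#' @export
local_max_detect <- function(bvp, config = local_max_config()) {
  stopifnot(inherits(bvp, "sampled_signal"), inherits(config, "local_max_config"))
  v <- bvp$values
  ma <- mean_abs(v)
  cand <- .local_maxima(v)
  cand <- cand[v[cand] >= config$min_height_factor * ma]
  if (length(cand) > 0) {
    prom <- prominence(bvp, cand)
    cand <- cand[prom >= config$min_prominence_factor * ma]
  }
  keep <- .enforce_min_distance(cand, v[cand], config$min_distance * bvp$fs)
  peak_series(bvp$t0 + (keep - 1) / bvp$fs, indices = keep, source = "local_max")
}

#' Topographic prominence of local maxima
#'
#' Standard topographic prominence: a peak's height minus the higher of the
#' two lowest valleys separating it from the nearest strictly higher sample
#' on each side; a record boundary counts as lower terrain (the valley
#' search simply extends to the edge).
#'
#' @param x A `sampled_signal` or numeric vector.
#' @param peak_indices Indices that must each be a strict local maximum.
#' @return Numeric vector of prominences, one per index.
#' @export
prominence <- function(x, peak_indices) {
  v <- if (inherits(x, "sampled_signal")) x$values else as.numeric(x)
  n <- length(v)
  vapply(as.integer(peak_indices), function(p) {
    if (p < 2L || p > n - 1L || v[p] <= v[p - 1L] || v[p] <= v[p + 1L])
      stop("index ", p, " is not a strict local maximum")
    h <- v[p]
    left <- Inf
    j <- p - 1L
    while (j >= 1L && v[j] < h) { left <- min(left, v[j]); j <- j - 1L }
    right <- Inf
    j <- p + 1L
    while (j <= n && v[j] < h) { right <- min(right, v[j]); j <- j + 1L }
    h - max(left, right)
  }, numeric(1))
}

# strict interior local maxima
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[v[i] > v[i - 1] & v[i] > v[i + 1]]
}

# Greedy minimum-distance enforcement: sort by height descending (ties to
# the earlier index), keep a candidate unless it lies strictly closer than
# min_dist samples to an already kept peak.
.enforce_min_distance <- function(idx, heights, min_dist_samples) {
  if (length(idx) == 0) return(integer(0))
  ord <- order(-heights, idx)
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) || all(abs(idx[k] - kept) >= min_dist_samples))
      kept <- c(kept, idx[k])
  }
  sort(kept)
}
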