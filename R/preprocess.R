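#' Center and detrend a signal or color trace
#'
#' Removes the slow trend and the mean from each channel before pulse
#' extraction and peak detection. Two trend models are available:
#'
#' * `"smoothness_prior"` (default): regularized least-squares smoothing
#'   with a second-difference penalty, the standard drift remover in HRV
#'   preprocessing. The penalty weight is derived from `cutoff_hz` (the
#'   approximate high-pass corner frequency) as
#'   `lambda = (fs / (2 * pi * cutoff_hz))^2`, unless `lambda` is given
#'   explicitly. The default 0.1 Hz corner removes illumination drift while
#'   leaving the heart-rate band (above ~0.65 Hz) essentially untouched.
#' * `"linear"`: ordinary least-squares straight-line detrend (an exact
#'   projection, hence idempotent).
#'
#' The output is always re-centered so each channel has zero mean.
#'
#' @param x A `sampled_signal`, `rgb_trace`, numeric vector or matrix.
#' @param method Trend model, `"smoothness_prior"` or `"linear"`.
#' @param cutoff_hz Approximate high-pass corner for the smoothness prior
#'   (Hz). Ignored when `lambda` is given or `method = "linear"`.
#' @param lambda Optional explicit smoothing weight for the smoothness
#'   prior (dimensionless; larger keeps slower trends).
#' @return The same type as `x`, centered and detrended; `fs` and `t0` are
#'   unchanged.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 1.2 * (0:499) / 25) + 0.01 * (0:499), fs = 25)
#' d <- center_detrend(s)
#' abs(mean(d$values)) < 1e-10
#' @export
center_detrend <- function(x, method = c("smoothness_prior", "linear"),
                           cutoff_hz = 0.1, lambda = NULL) {
  UseMethod("center_detrend")
}

#' @export
center_detrend.sampled_signal <- function(x, method = c("smoothness_prior", "linear"),
                                          cutoff_hz = 0.1, lambda = NULL) {
  method <- match.arg(method)
  x$values <- .detrend_vec(x$values, x$fs, method, cutoff_hz, lambda)
  x
}

#' @export
center_detrend.rgb_trace <- function(x, method = c("smoothness_prior", "linear"),
                                     cutoff_hz = 0.1, lambda = NULL) {
  method <- match.arg(method)
  x$values <- apply(x$values, 2, .detrend_vec, fs = x$fs, method = method,
                    cutoff_hz = cutoff_hz, lambda = lambda)
  colnames(x$values) <- c("r", "g", "b")
  x
}

#' @export
center_detrend.default <- function(x, method = c("smoothness_prior", "linear"),
                                   cutoff_hz = 0.1, lambda = NULL) {
  method <- match.arg(method)
  if (is.matrix(x)) {
    apply(x, 2, .detrend_vec, fs = 1, method = method,
          cutoff_hz = cutoff_hz, lambda = lambda)
  } else {
    .detrend_vec(as.numeric(x), 1, method, cutoff_hz, lambda)
  }
}

.detrend_vec <- function(v, fs, method, cutoff_hz, lambda) {
  .check_finite(v, "values")
  n <- length(v)
  if (n < 3) stop("need at least 3 samples to detrend")
  trend <- if (method == "linear") {
    i <- seq_len(n)
    stats::lm.fit(cbind(1, i), v)$fitted.values
  } else {
    .smoothness_trend(v, fs, cutoff_hz, lambda)
  }
  r <- v - trend
  r - mean(r)
}

# Regularized LS trend: argmin ||v - z||^2 + lambda^2 ||D2 z||^2, solved on
# the sparse pentadiagonal normal equations.
.smoothness_trend <- function(v, fs, cutoff_hz, lambda = NULL) {
  n <- length(v)
  if (is.null(lambda)) {
    .check_scalar(cutoff_hz, "cutoff_hz", positive = TRUE)
    lambda <- (fs / (2 * pi * cutoff_hz))^2
  }
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
  as.numeric(Matrix::solve(A, v))
}

#' Mean absolute value of a signal
#'
#' The amplitude statistic that parameterizes the rule-based detectors'
#' thresholds: `(1/T) * sum(|values|)` of the detrended signal.
#'
#' @param x A `sampled_signal` or numeric vector.
#' @return Non-negative scalar in signal units.
#' @examples
#' mean_abs(c(3, -4)) # 3.5
#' @export
mean_abs <- function(x) {
  v <- if (inherits(x, "sampled_signal")) x$values else as.numeric(x)
  if (length(v) < 1) stop("empty signal")
  .check_finite(v, "values")
  mean(abs(v))
}
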