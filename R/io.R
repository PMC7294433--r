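#' Read a color trace or single-channel signal from CSV
#'
#' Reads `time,r,g,b` (trace) or `time,value` (signal) CSV files with a
#' header row. Time must be in seconds, strictly increasing and uniform
#' within 1e-6 relative tolerance; the sampling rate is inferred from the
#' median time step.
#'
#' @param path CSV file path.
#' @return An `rgb_trace` or `sampled_signal` depending on the header.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  fs <- .infer_fs(df$time, path)
  if (all(c("r", "g", "b") %in% names(df))) {
    rgb_trace(cbind(df$r, df$g, df$b), fs = fs, t0 = df$time[1])
  } else if ("value" %in% names(df)) {
    sampled_signal(df$value, fs = fs, t0 = df$time[1])
  } else {
    stop("expected header 'time,r,g,b' or 'time,value' in ", path)
  }
}

#' @rdname read_trace_csv
#' @export
read_signal_csv <- function(path) {
  x <- read_trace_csv(path)
  if (!inherits(x, "sampled_signal"))
    stop("expected a single-channel 'time,value' file: ", path)
  x
}

#' Write a signal or trace to CSV
#'
#' @param x A `sampled_signal` (written as `time,value`) or `rgb_trace`
#'   (written as `time,r,g,b`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_signal_csv <- function(x, path) {
  t <- signal_times(x)
  df <- if (inherits(x, "rgb_trace")) {
    data.frame(time = t, r = x$values[, 1], g = x$values[, 2], b = x$values[, 3])
  } else {
    data.frame(time = t, value = x$values)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write peak time series CSV (`index,time_s` header)
#'
#' @param path CSV file path.
#' @param source Peak source label for the returned series.
#' @return [read_peaks_csv()] returns a `peak_series`.
#' @export
read_peaks_csv <- function(path, source = "ground_truth") {
  df <- read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!"time_s" %in% names(df))
    stop("expected header 'index,time_s' in ", path)
  idx <- if ("index" %in% names(df) && !anyNA(df$index)) df$index else NULL
  peak_series(df$time_s, indices = idx, source = source)
}

#' @rdname read_peaks_csv
#' @param peaks A `peak_series` to write.
#' @export
write_peaks_csv <- function(peaks, path) {
  idx <- if (is.null(peaks$indices)) rep(NA_integer_, length(peaks$times)) else peaks$indices
  write.csv(data.frame(index = idx, time_s = peaks$times), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

.infer_fs <- function(time, path) {
  if (is.null(time)) stop("missing 'time' column in ", path)
  if (length(time) < 2) stop("need at least 2 rows in ", path)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing in ", path,
                         " (first violation at row ", which(dt <= 0)[1] + 1, ")")
  med <- stats::median(dt)
  if (any(abs(dt - med) > 1e-6 * med))
    stop("non-uniform sampling in ", path, " (tolerance 1e-6 relative)")
  1 / med
}
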