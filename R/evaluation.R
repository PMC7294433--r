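#' Match detected peaks to ground-truth peaks
#'
#' One-to-one matching within a symmetric search range (default 0.2 s,
#' wide enough to absorb the pulse transit delay between a contact sensor
#' and the face): all candidate (truth, detected) pairs within range are
#' sorted by ascending absolute time difference and accepted greedily,
#' each peak being used at most once. Leftover detections count as
#' incorrect peaks, leftover truth peaks as missing.
#'
#' @param detected,truth `peak_series` objects (sorted by construction).
#' @param search_range Matching half-window in seconds (default 0.2).
#' @return List of class `match_result`: `pairs` (data frame with
#'   `truth_time`, `detected_time`, `dt`, `truth_pos`, `detected_pos`),
#'   `n_truth`, `n_detected`, `unmatched_truth`, `unmatched_detected`,
#'   `search_range`.
#' @export
match_peaks <- function(detected, truth, search_range = 0.2) {
  stopifnot(inherits(detected, "peak_series"), inherits(truth, "peak_series"))
  tt <- truth$times
  dt_ <- detected$times
  if (length(tt) == 0) stop("empty ground-truth series: metrics undefined")
  pairs <- data.frame(truth_pos = integer(0), detected_pos = integer(0),
                      truth_time = numeric(0), detected_time = numeric(0),
                      dt = numeric(0))
  if (length(dt_) > 0) {
    d <- abs(outer(tt, dt_, "-"))
    cand <- which(d <= search_range, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      used_t <- logical(length(tt))
      used_d <- logical(length(dt_))
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_t[i] && !used_d[j]) {
          used_t[i] <- TRUE; used_d[j] <- TRUE; keep[k] <- TRUE
        }
      }
      m <- cand[keep, , drop = FALSE]
      m <- m[order(m[, 1]), , drop = FALSE]
      pairs <- data.frame(truth_pos = m[, 1], detected_pos = m[, 2],
                          truth_time = tt[m[, 1]], detected_time = dt_[m[, 2]],
                          dt = dt_[m[, 2]] - tt[m[, 1]])
    }
  }
  structure(list(pairs = pairs,
                 n_truth = length(tt), n_detected = length(dt_),
                 unmatched_truth = tt[setdiff(seq_along(tt), pairs$truth_pos)],
                 unmatched_detected = dt_[setdiff(seq_along(dt_), pairs$detected_pos)],
                 search_range = search_range),
            class = "match_result")
}

#' Peak detection error metrics
#'
#' Location error and detection proportions from a peak matching:
#' `PLE` = mean absolute time difference over matched pairs (NA when there
#' are none); `%CP` = matched / truth, `%MP` = missing / truth,
#' `%IP` = extra detections / truth, all in percent of the number of
#' ground-truth peaks (so `%CP + %MP = 100` and `%IP` may exceed 100 in
#' pathological cases).
#'
#' @param match A `match_result`.
#' @return List with `ple_s`, `pct_cp`, `pct_ip`, `pct_mp`.
#' @export
peak_metrics <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (match$n_truth < 1) stop("no ground-truth peaks")
  np <- nrow(match$pairs)
  list(ple_s = if (np > 0) mean(abs(match$pairs$dt)) else NA_real_,
       pct_cp = 100 * np / match$n_truth,
       pct_ip = 100 * length(match$unmatched_detected) / match$n_truth,
       pct_mp = 100 * length(match$unmatched_truth) / match$n_truth)
}

#' Interval and PRV series errors between detected and truth peaks
#'
#' `IBIer`: mean absolute difference between inter-beat intervals formed
#' from consecutive matched peak pairs -- an interval contributes only when
#' its two bounding peaks are adjacent in *both* series, so missed or extra
#' beats break the comparison chain rather than corrupting it.
#' `PRVer`: mean absolute difference between the two interpolated PRV
#' series (at `fs_out`) over their overlapping time support.
#' `%PRVer`: `PRVer` as a percentage of the mean ground-truth PRV value
#' over the same support.
#'
#' @param detected,truth `peak_series` objects with >= 3 peaks each.
#' @param match Optional precomputed `match_result` (computed if NULL).
#' @param search_range Matching half-window in seconds.
#' @param fs_out PRV interpolation rate in Hz.
#' @param method PRV interpolation method.
#' @return List with `ibier_s`, `prver_s`, `pct_prver`.
#' @export
prv_errors <- function(detected, truth, match = NULL, search_range = 0.2,
                       fs_out = 200, method = "cubic_spline") {
  if (is.null(match)) match <- match_peaks(detected, truth, search_range)
  ibi_d <- ibi_from_peaks(detected)
  ibi_t <- ibi_from_peaks(truth)

  p <- match$pairs
  ibier <- NA_real_
  if (nrow(p) >= 2) {
    adj <- diff(p$truth_pos) == 1L & diff(p$detected_pos) == 1L
    if (any(adj)) {
      k <- which(adj)
      d_iv <- p$detected_time[k + 1] - p$detected_time[k]
      t_iv <- p$truth_time[k + 1] - p$truth_time[k]
      ibier <- mean(abs(d_iv - t_iv))
    }
  }

  meth <- if (length(ibi_d$intervals) < 4 || length(ibi_t$intervals) < 4) "linear" else method
  lo <- max(ibi_d$anchor_times[1], ibi_t$anchor_times[1])
  hi <- min(ibi_d$anchor_times[length(ibi_d$anchor_times)],
            ibi_t$anchor_times[length(ibi_t$anchor_times)])
  if (hi <= lo) stop("no overlapping PRV support between detected and truth series")
  grid <- lo + (0:floor((hi - lo) * fs_out + 1e-9)) / fs_out
  vd <- .prv_interpolant(ibi_d$anchor_times, ibi_d$intervals, meth)(grid)
  vt <- .prv_interpolant(ibi_t$anchor_times, ibi_t$intervals, meth)(grid)
  prver <- mean(abs(vd - vt))
  list(ibier_s = ibier, prver_s = prver, pct_prver = 100 * prver / mean(vt))
}

#' Absolute errors of PRV features
#'
#' @param detected_features,truth_features `prv_features` (or any lists
#'   with `std_ibi` and `rmssd` entries, in seconds).
#' @return List with `stder_s` and `rmssder_s` (absolute differences).
#' @examples
#' feature_errors(list(std_ibi = 0.1142, rmssd = 0.13),
#'                list(std_ibi = 0.0631, rmssd = 0.067))$stder_s # 0.0511
#' @export
feature_errors <- function(detected_features, truth_features) {
  list(stder_s = abs(detected_features$std_ibi - truth_features$std_ibi),
       rmssder_s = abs(detected_features$rmssd - truth_features$rmssd))
}

#' Full evaluation report for one recording
#'
#' Computes every error metric between a detected peak series and its
#' ground truth: peak location error and detection proportions, interval
#' and PRV series errors, and feature errors (interval standard deviation
#' and RMSSD).
#'
#' @inheritParams prv_errors
#' @return List of class `evaluation_report` with `ple_s`, `pct_cp`,
#'   `pct_ip`, `pct_mp`, `ibier_s`, `prver_s`, `pct_prver`, `stder_s`,
#'   `rmssder_s`.
#' @export
evaluate_detection <- function(detected, truth, search_range = 0.2,
                               fs_out = 200, method = "cubic_spline") {
  m <- match_peaks(detected, truth, search_range)
  pm <- peak_metrics(m)
  pe <- prv_errors(detected, truth, match = m, fs_out = fs_out, method = method)
  fe <- feature_errors(prv_features(detected, fs_out = fs_out, method = method),
                       prv_features(truth, fs_out = fs_out, method = method))
  structure(c(pm, pe, fe), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report>\n",
                     "  PLE = %.4f s   %%CP = %.2f   %%MP = %.2f   %%IP = %.2f\n",
                     "  IBIer = %.4f s   PRVer = %.4f s   %%PRVer = %.2f\n",
                     "  STDer = %.4f s   RMSSDer = %.4f s\n"),
              x$ple_s, x$pct_cp, x$pct_mp, x$pct_ip,
              x$ibier_s, x$prver_s, x$pct_prver, x$stder_s, x$rmssder_s))
  invisible(x)
}

#' Aggregate per-recording metrics into cohort mean and confidence interval
#'
#' For each shared numeric metric, the mean across recordings and the
#' 95% (by default) confidence half-width `t(1-(1-level)/2, n-1) * sd / sqrt(n)`
#' (Student-t based). Metrics missing (NA) in some recordings are averaged
#' over the recordings that provide them.
#'
#' @param reports List of `evaluation_report` / `prv_features` / named
#'   numeric lists.
#' @param level Confidence level (default 0.95).
#' @return Data frame of class `cohort_summary` with columns `metric`,
#'   `mean`, `ci_half_width`, `n`.
#' @export
aggregate_reports <- function(reports, level = 0.95) {
  if (length(reports) < 1) stop("need at least one report")
  metrics <- Reduce(union, lapply(reports, names))
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) {
      x <- r[[m]]
      if (is.null(x) || !is.numeric(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0) return(NULL)
    hw <- if (n >= 2) qt(1 - (1 - level) / 2, n - 1) * sd(v) / sqrt(n) else NA_real_
    data.frame(metric = m, mean = mean(v), ci_half_width = hw, n = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", class(out))
  attr(out, "level") <- level
  out
}
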