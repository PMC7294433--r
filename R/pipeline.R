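#' Default run configuration
#'
#' One flat list of every tunable parameter of the extraction / detection /
#' PRV pipeline, with the detectors' published defaults: peak window factor
#' 0.25 and 10 s FFT window (two-window), SSF window 0.4 s with height
#' factor 0.175, local-max height 0.75 and prominence 0.3 times the mean
#' absolute amplitude, 0.24 s minimum peak distance, 0.2 s match search
#' range, and 200 Hz PRV interpolation.
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    hr_band_bpm = c(40, 240),
    detector = "two_window",
    detrend_method = "smoothness_prior",
    detrend_cutoff_hz = 0.1,
    ridge = 1e-8,
    pvm_window_s = NULL,
    fft_window_s = 10,
    wp_factor = 0.25,
    ssf_window_s = 0.4,
    ssf_height_factor = 0.175,
    min_height_factor = 0.75,
    min_prominence_factor = 0.3,
    min_distance_s = 0.24,
    search_range_s = 0.2,
    fs_out = 200,
    interp_method = "cubic_spline",
    seed = 1L,
    log_level = "info"
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Values present in the file override the defaults; unknown keys are an
#' error (they are almost always typos).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional named list applied on top of the file
#'   (CLI-flag precedence: overrides > file > defaults).
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  apply_over <- function(cfg, vals, src) {
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown) > 0)
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    for (k in names(vals)) cfg[k] <- list(vals[[k]])  # keeps explicit NULLs
    cfg
  }
  if (!is.null(path)) cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  if (!is.null(overrides)) cfg <- apply_over(cfg, overrides, "overrides")
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full extraction / detection / PRV pipeline on one recording
#'
#' Stages: read the trace CSV (`time,r,g,b`; a `time,value` file skips
#' extraction), center/detrend, PVM extraction, sign fix, peak detection
#' with the configured detector, IBI and 200 Hz PRV construction, feature
#' extraction, and -- when a ground-truth peak CSV is supplied -- the full
#' evaluation report. The run is deterministic given inputs and
#' configuration; the returned object (and the JSON written to
#' `report_path`) embeds the effective configuration for provenance.
#'
#' @param trace_path CSV path of the color trace or single-channel signal.
#' @param truth_path Optional CSV path of ground-truth peaks
#'   (`index,time_s`).
#' @param config A `run_config` (see [default_config()], [load_config()]).
#' @param report_path Optional path; the result is written there as JSON.
#' @param keep_intermediates Optional directory; when set, the detrended
#'   BVP (`bvp.csv`) and detected peaks (`peaks.csv`) are written into it.
#' @return List of class `pipeline_result` with `schema = 1`, `config`,
#'   `extraction` (tau*, rho*, w, flag; NULL for single-channel input),
#'   `n_peaks`, `features`, and `report` (NULL without ground truth).
#' @export
run_pipeline <- function(trace_path, truth_path = NULL,
                         config = default_config(),
                         report_path = NULL, keep_intermediates = NULL) {
  stopifnot(inherits(config, "run_config"))
  hr_band <- config$hr_band_bpm / 60
  x <- read_trace_csv(trace_path)
  x <- center_detrend(x, method = config$detrend_method,
                      cutoff_hz = config$detrend_cutoff_hz)
  extraction <- NULL
  if (inherits(x, "rgb_trace")) {
    res <- extract_bvp(x, hr_band = hr_band, ridge = config$ridge,
                       window_s = config$pvm_window_s)
    bvp <- res$bvp
    extraction <- list(tau_star = res$tau_star, tau_star_s = res$tau_star_s,
                       rho_star = res$rho_star, w = res$w,
                       low_periodicity = res$low_periodicity)
  } else {
    bvp <- fix_sign(x)
  }
  peaks <- switch(config$detector,
    two_window = two_window_detect(bvp, hr_band = hr_band,
                                   fft_window_s = config$fft_window_s,
                                   wp_factor = config$wp_factor)$peaks,
    ssf = ssf_detect(bvp, w_ssf = config$ssf_window_s,
                     height_factor = config$ssf_height_factor,
                     min_distance = config$min_distance_s,
                     detrend_method = config$detrend_method),
    local_max = local_max_detect(bvp,
      config = local_max_config(config$min_height_factor,
                                config$min_prominence_factor,
                                config$min_distance_s)),
    stop("unknown detector: ", config$detector))
  if (!is.null(keep_intermediates)) {
    dir.create(keep_intermediates, recursive = TRUE, showWarnings = FALSE)
    write_signal_csv(bvp, file.path(keep_intermediates, "bvp.csv"))
    write_peaks_csv(peaks, file.path(keep_intermediates, "peaks.csv"))
  }
  if (length(peaks$times) < 3)
    stop("detection stage produced fewer than 3 peaks; cannot compute PRV")
  features <- prv_features(peaks, fs_out = config$fs_out,
                           method = config$interp_method)
  report <- NULL
  if (!is.null(truth_path)) {
    truth <- read_peaks_csv(truth_path)
    report <- evaluate_detection(peaks, truth,
                                 search_range = config$search_range_s,
                                 fs_out = config$fs_out,
                                 method = config$interp_method)
  }
  out <- structure(list(schema = 1L, config = unclass(config),
                        extraction = extraction,
                        n_peaks = length(peaks$times),
                        features = unclass(features),
                        report = if (is.null(report)) NULL else unclass(report)),
                   class = "pipeline_result")
  if (!is.null(report_path)) {
    jsonlite::write_json(unclass(out), report_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> detector = %s, %d peaks\n",
              x$config$detector, x$n_peaks))
  if (!is.null(x$extraction))
    cat(sprintf("  PVM: tau* = %.3f s, rho* = %.4f\n",
                x$extraction$tau_star_s, x$extraction$rho_star))
  cat(sprintf("  features: std_ibi = %.4f s, rmssd = %.4f s\n",
              x$features$std_ibi, x$features$rmssd))
  if (!is.null(x$report))
    cat(sprintf("  vs truth: %%CP = %.2f, PLE = %.4f s, %%PRVer = %.2f\n",
                x$report$pct_cp, x$report$ple_s, x$report$pct_prver))
  invisible(x)
}
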