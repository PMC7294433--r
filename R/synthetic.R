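#' Parametric pulse waveform model
#'
#' Describes the quasi-periodic cardiac pulse the generators render: a mean
#' heart rate whose instantaneous value is modulated by a respiratory
#' (RSA) rhythm and a slower low-frequency rhythm, with each beat drawn as
#' an asymmetric pair of Gaussian bumps (systolic peak plus a delayed,
#' smaller dicrotic bump riding the falling limb).
#'
#' Modulation depths are expressed in seconds of inter-beat-interval
#' deviation, so `rsa_depth = 0.05` programs +-0.05 s of beat-to-beat
#' interval swing at `rsa_freq`.
#'
#' @param mean_hr Mean heart rate in bpm, within \[40, 240\].
#' @param rsa_freq Respiratory modulation frequency in Hz (default 0.25).
#' @param rsa_depth Respiratory IBI modulation depth in seconds.
#' @param lf_freq Low-frequency modulation in Hz (default 0.1).
#' @param lf_depth Low-frequency IBI modulation depth in seconds.
#' @param systolic_width Gaussian sigma of the systolic bump in seconds.
#' @param dicrotic_amp Dicrotic bump amplitude relative to the systolic.
#' @param dicrotic_delay Dicrotic bump delay after the systolic apex (s).
#' @return List of class `pulse_model`.
#' @export
pulse_model <- function(mean_hr = 72, rsa_freq = 0.25, rsa_depth = 0.03,
                        lf_freq = 0.1, lf_depth = 0.02,
                        systolic_width = 0.13, dicrotic_amp = 0.3,
                        dicrotic_delay = 0.3) {
  if (mean_hr < 40 || mean_hr > 240) stop("mean_hr must lie in [40, 240] bpm")
  if (rsa_depth < 0 || lf_depth < 0) stop("modulation depths must be >= 0")
  if (systolic_width <= 0 || dicrotic_delay < 0 || dicrotic_amp < 0)
    stop("waveform parameters must be positive")
  structure(list(mean_hr = mean_hr, rsa_freq = rsa_freq, rsa_depth = rsa_depth,
                 lf_freq = lf_freq, lf_depth = lf_depth,
                 systolic_width = systolic_width, dicrotic_amp = dicrotic_amp,
                 dicrotic_delay = dicrotic_delay),
            class = "pulse_model")
}

#' Signal corruption model
#'
#' Degradations applied to generated recordings: additive white Gaussian
#' noise at a target SNR, slow sinusoidal baseline drift (amplitude
#' relative to the clean signal's AC RMS), and per-beat amplitude collapse
#' -- each beat is attenuated to `collapse_factor` of its height with
#' probability `collapse_prob`, reproducing the low-beat failure mode that
#' defeats fixed-height peak rules.
#'
#' @param snr_db Signal-to-noise ratio in dB (`Inf` disables noise).
#' @param drift_amp Drift amplitude relative to the AC RMS (0 disables).
#' @param drift_freq Drift frequency in Hz.
#' @param collapse_prob Per-beat probability of amplitude collapse, in
#'   \[0, 1\].
#' @param collapse_factor Collapsed amplitude as a fraction of normal, in
#'   (0, 1\].
#' @return List of class `corruption_model`.
#' @export
corruption_model <- function(snr_db = 10, drift_amp = 0.5, drift_freq = 0.05,
                             collapse_prob = 0, collapse_factor = 0.3) {
  if (collapse_prob < 0 || collapse_prob > 1) stop("collapse_prob must lie in [0, 1]")
  if (collapse_factor <= 0 || collapse_factor > 1) stop("collapse_factor must lie in (0, 1]")
  if (drift_amp < 0) stop("drift_amp must be >= 0")
  structure(list(snr_db = snr_db, drift_amp = drift_amp, drift_freq = drift_freq,
                 collapse_prob = collapse_prob, collapse_factor = collapse_factor),
            class = "corruption_model")
}

#' @rdname corruption_model
#' @export
no_corruption <- function() {
  corruption_model(snr_db = Inf, drift_amp = 0, collapse_prob = 0)
}

#' Simulate a single-channel BVP recording with ground truth
#'
#' Beat times come from integrating an instantaneous heart rate whose
#' period is modulated at the model's RSA and LF frequencies (cumulative
#' phase on a 1 ms grid; beats at integer phase crossings, linearly
#' interpolated). Each beat is rendered as the model's two-bump waveform;
#' per-beat collapse, sinusoidal drift and white noise are then applied.
#' The ground truth records the exact apex times of the clean rendered
#' waveform (refined by numeric maximization per beat), the implied IBI
#' sequence and the unmodulated period.
#'
#' Beats closer than 0.3 s to the start or 0.4 s to the end of the record
#' are not generated, so every ground-truth beat is fully rendered.
#'
#' @param model A [pulse_model()].
#' @param duration Record length in seconds (>= 10).
#' @param fs Sampling rate in Hz.
#' @param corruption A [corruption_model()].
#' @param seed Optional integer seed; the same seed reproduces the
#'   recording bitwise.
#' @return List with `signal` (`sampled_signal`) and `truth`
#'   (`ground_truth`: `peak_times`, `ibi`, `mixing_vector`,
#'   `true_period_s`).
#' @examples
#' sim <- simulate_bvp(pulse_model(mean_hr = 60, rsa_depth = 0, lf_depth = 0),
#'                     duration = 12, fs = 25, corruption = no_corruption())
#' diff(sim$truth$peak_times) # all 1.0
#' @export
simulate_bvp <- function(model, duration, fs, corruption = corruption_model(),
                         seed = NULL) {
  stopifnot(inherits(model, "pulse_model"), inherits(corruption, "corruption_model"))
  if (duration < 10) stop("duration must be >= 10 s")
  run <- function() {
    bt <- .beat_times(model, duration)
    amps <- .collapse_amps(length(bt), corruption)
    f <- .beat_waveform_fun(bt, amps, model)
    apex <- .refine_apexes(f, bt, model)
    n <- round(duration * fs)
    t <- (0:(n - 1)) / fs
    clean <- f(t)
    sig <- .corrupt(clean, t, corruption)
    list(signal = sampled_signal(sig, fs = fs),
         truth = .ground_truth(apex, NULL, model))
  }
  .with_optional_seed(seed, run)
}

#' Simulate a 3-channel color trace embedding a pulse
#'
#' The clean BVP waveform is mixed into the three channels by a fixed
#' mixing vector (outer product), then each channel independently receives
#' drift (random phase) and white noise at the requested SNR -- the input
#' contract of [extract_bvp()].
#'
#' @inheritParams simulate_bvp
#' @param mixing Non-zero length-3 channel mixing vector.
#' @return List with `trace` (`rgb_trace`) and `truth` (`ground_truth`
#'   carrying the mixing vector and true period).
#' @export
simulate_rgb <- function(model, mixing = c(0.3, 1, 0.5), duration, fs,
                         corruption = corruption_model(), seed = NULL) {
  stopifnot(inherits(model, "pulse_model"), inherits(corruption, "corruption_model"))
  if (length(mixing) != 3 || all(mixing == 0)) stop("mixing must be a non-zero 3-vector")
  if (duration < 10) stop("duration must be >= 10 s")
  run <- function() {
    bt <- .beat_times(model, duration)
    amps <- .collapse_amps(length(bt), corruption)
    f <- .beat_waveform_fun(bt, amps, model)
    apex <- .refine_apexes(f, bt, model)
    n <- round(duration * fs)
    t <- (0:(n - 1)) / fs
    clean <- f(t)
    X <- outer(clean, as.numeric(mixing))
    for (ch in 1:3) {
      X[, ch] <- .corrupt(X[, ch], t, corruption)
    }
    list(trace = rgb_trace(X, fs = fs),
         truth = .ground_truth(apex, as.numeric(mixing), model))
  }
  .with_optional_seed(seed, run)
}

#' Simulate a synchronized contact / remote recording pair
#'
#' One underlying beat sequence rendered twice: a clean single-channel
#' contact reference at `fs_contact`, and a remote 3-channel trace at
#' `fs_video` whose beats are shifted by a pulse-transit `delay` and
#' corrupted by `corruption_remote`. Ground-truth peak times are provided
#' for both renderings.
#'
#' @inheritParams simulate_rgb
#' @param corruption_remote Corruption applied to the remote trace.
#' @param fs_contact Contact sampling rate in Hz (default 1000).
#' @param fs_video Remote (camera) sampling rate in Hz (default 25).
#' @param delay Remote-minus-contact pulse delay in seconds, |delay| < 0.2.
#' @return List with `contact` (list of `signal`, `truth`) and `remote`
#'   (list of `trace`, `truth`).
#' @export
simulate_pair <- function(model, corruption_remote = corruption_model(),
                          duration = 30, fs_contact = 1000, fs_video = 25,
                          delay = 0, mixing = c(0.3, 1, 0.5), seed = NULL) {
  stopifnot(inherits(model, "pulse_model"))
  if (abs(delay) >= 0.2) stop("|delay| must be < 0.2 s")
  if (duration < 10) stop("duration must be >= 10 s")
  run <- function() {
    T0 <- 60 / model$mean_hr
    bt <- .beat_times(model, duration,
                      start_margin = max(0.3, 0.7 * T0) + max(0, -delay),
                      end_margin = max(0.4, 0.7 * T0) + max(0, delay))
    # contact: clean, no collapse
    fc <- .beat_waveform_fun(bt, rep(1, length(bt)), model)
    apex_c <- .refine_apexes(fc, bt, model)
    nc <- round(duration * fs_contact)
    tc <- (0:(nc - 1)) / fs_contact
    contact <- list(signal = sampled_signal(fc(tc), fs = fs_contact),
                    truth = .ground_truth(apex_c, NULL, model))
    # remote: delayed, collapsed, corrupted
    btr <- bt + delay
    amps <- .collapse_amps(length(btr), corruption_remote)
    fr <- .beat_waveform_fun(btr, amps, model)
    apex_r <- .refine_apexes(fr, btr, model)
    nv <- round(duration * fs_video)
    tv <- (0:(nv - 1)) / fs_video
    X <- outer(fr(tv), as.numeric(mixing))
    for (ch in 1:3) X[, ch] <- .corrupt(X[, ch], tv, corruption_remote)
    remote <- list(trace = rgb_trace(X, fs = fs_video),
                   truth = .ground_truth(apex_r, as.numeric(mixing), model))
    list(contact = contact, remote = remote)
  }
  .with_optional_seed(seed, run)
}

## ---- internals ----

.with_optional_seed <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}

.ground_truth <- function(apex, mixing, model) {
  structure(list(peak_times = apex,
                 ibi = diff(apex),
                 mixing_vector = mixing,
                 true_period_s = 60 / model$mean_hr),
            class = "ground_truth")
}

# Beat times by cumulative-phase integration of the instantaneous rate on a
# 1 ms grid; modulation depths (seconds of IBI) are converted to relative
# frequency modulation so programmed frequencies appear at the programmed
# Hz in the IBI spectrum. Beats are kept clear of the record edges by at
# least ~0.7 beat periods so every ground-truth beat is fully rendered and
# outside the zone where centered-window statistics are edge-biased.
.beat_times <- function(model, duration, dt = 1e-3,
                        start_margin = NULL, end_margin = NULL) {
  T0 <- 60 / model$mean_hr
  f0 <- 1 / T0
  if (is.null(start_margin)) start_margin <- max(0.3, 0.7 * T0)
  if (is.null(end_margin)) end_margin <- max(0.4, 0.7 * T0)
  tg <- seq(0, duration, by = dt)
  finst <- f0 * (1 - (model$rsa_depth / T0) * sin(2 * pi * model$rsa_freq * tg)
                   - (model$lf_depth / T0) * sin(2 * pi * model$lf_freq * tg))
  if (any(finst <= 0))
    stop("modulation depths too large: instantaneous rate becomes non-positive")
  m <- length(finst)
  phase <- cumsum(c(0, (finst[-1] + finst[-m]) / 2 * dt))
  k <- seq_len(floor(phase[m]))
  if (length(k) < 2) stop("record too short for the requested heart rate")
  bt <- approx(phase, tg, xout = k)$y
  bt <- bt[bt >= start_margin & bt <= duration - end_margin]
  if (length(bt) < 2) stop("record too short: fewer than 2 beats survive the edge margins")
  if (any(diff(bt) < 0.25 - 1e-9))
    stop("generated inter-beat intervals fall below 0.25 s; reduce modulation depths or heart rate")
  bt
}

.collapse_amps <- function(n_beats, corruption) {
  amps <- rep(1, n_beats)
  if (corruption$collapse_prob > 0) {
    hit <- runif(n_beats) < corruption$collapse_prob
    amps[hit] <- corruption$collapse_factor
  }
  amps
}

.beat_waveform_fun <- function(bt, amps, model) {
  s <- model$systolic_width
  d <- model$dicrotic_delay
  a <- model$dicrotic_amp
  function(t) {
    out <- numeric(length(t))
    for (k in seq_along(bt)) {
      out <- out + amps[k] * (exp(-0.5 * ((t - bt[k]) / s)^2) +
                              a * exp(-0.5 * ((t - bt[k] - d) / s)^2))
    }
    out
  }
}

.refine_apexes <- function(f, bt, model) {
  s <- model$systolic_width
  vapply(bt, function(b)
    optimize(f, c(b - s, b + s), maximum = TRUE, tol = 1e-7)$maximum,
    numeric(1))
}

.corrupt <- function(v, t, corruption) {
  rms_ac <- sd(v)
  if (corruption$drift_amp > 0) {
    ph <- runif(1, 0, 2 * pi)
    v <- v + corruption$drift_amp * rms_ac * sin(2 * pi * corruption$drift_freq * t + ph)
  }
  if (is.finite(corruption$snr_db)) {
    nsd <- rms_ac / 10^(corruption$snr_db / 20)
    v <- v + rnorm(length(v), 0, nsd)
  }
  v
}
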