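test_that("estimate_beat_window recovers the period of a pure sinusoid", {
  fs <- 25
  t <- (0:(30 * fs - 1)) / fs
  s <- sampled_signal(sin(2 * pi * 1.2 * t), fs = fs)
  Wb <- estimate_beat_window(s)
  # one zero-padded FFT bin (fs / (4 * win) = 0.025 Hz) maps to ~0.017 s
  # of period uncertainty at 1.2 Hz
  expect_true(all(abs(Wb - 1 / 1.2) < 0.02))
})

test_that("estimate_beat_window tracks a chirp monotonically", {
  fs <- 25
  t <- (0:(60 * fs - 1)) / fs
  # linear chirp 1 -> 2 Hz over 60 s
  phase <- 2 * pi * (t + t^2 / 120)
  s <- sampled_signal(sin(phase), fs = fs)
  Wb <- estimate_beat_window(s)
  interior <- (10 * fs):(50 * fs)
  # non-increasing up to one padded-bin step (~0.025 s at the low end)
  expect_true(all(diff(Wb[interior]) <= 0.03))
  expect_lt(Wb[45 * fs], Wb[15 * fs])
})

test_that("all-zero windows fall back to the band midpoint with a warning", {
  s <- sampled_signal(rep(0, 300), fs = 25)
  expect_warning(Wb <- estimate_beat_window(s), "band midpoint")
  mid <- sqrt((40 / 60) * (240 / 60))
  expect_equal(unique(Wb), 1 / mid)
})

test_that("moving_average handles constants, identity windows and ramps", {
  expect_equal(moving_average(rep(2.5, 20), 7), rep(2.5, 20))
  set.seed(1)
  v <- rnorm(30)
  expect_equal(moving_average(v, 1), v)
  ramp <- seq(0, 5, length.out = 50)
  ma <- moving_average(ramp, 9)
  expect_equal(ma[5:46], ramp[5:46], tolerance = 1e-12)  # interior unchanged
  expect_message(moving_average(v, 4), "odd")
  s <- sampled_signal(v, fs = 25)
  expect_s3_class(moving_average(s, 5), "sampled_signal")
  # per-sample varying windows agree with direct evaluation
  w <- rep(c(3L, 5L, 7L), length.out = 30)
  got <- moving_average(v, w)
  want <- vapply(seq_along(v), function(i) {
    h <- (w[i] - 1) / 2
    mean(v[max(1, i - h):min(30, i + h)])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("two-window detection finds every beat of a clean pulse train", {
  cl <- make_clean_pulse(hr = 60, duration = 30, fs = 25, seed = 5)
  res <- two_window_detect(cl$bvp)
  m <- match_peaks(res$peaks, cl$truth, search_range = 0.1)
  expect_equal(nrow(m$pairs), length(cl$truth$times))
  expect_true(all(abs(m$pairs$dt) <= 1 / 25 + 1e-9))  # within one sample
  # structural invariants of the surviving blocks
  st <- res$state
  expect_true(all(st$blocks$width >= st$THR2))
  expect_equal(st$THR1, st$MAb)
  for (k in seq_along(res$peaks$indices)) {
    i <- res$peaks$indices[k]
    b <- st$blocks[st$blocks$start <= i & st$blocks$end >= i, ]
    expect_equal(nrow(b), 1)
    expect_true(any(st$MAp[b$start:b$end] > st$MAb[b$start:b$end]))
  }
})

test_that("two-window detection returns nothing on a constant signal", {
  res <- suppressWarnings(two_window_detect(sampled_signal(rep(0, 750), fs = 25)))
  expect_length(res$peaks$times, 0)
})

test_that("narrow noise spikes are rejected by the block-width threshold", {
  cl <- make_clean_pulse(hr = 60, duration = 30, fs = 25, seed = 9)
  v <- cl$bvp$values
  # 2-sample-wide spike between two beats
  mid <- which.min(abs(signal_times(cl$bvp) - (cl$truth$times[10] + 0.5)))
  spike <- v
  spike[mid + 0:1] <- max(v) * 1.5
  res <- two_window_detect(sampled_signal(spike, fs = 25))
  m <- match_peaks(res$peaks, cl$truth, search_range = 0.1)
  expect_equal(nrow(m$pairs), length(cl$truth$times))
  # no detection at the spike
  expect_false(any(abs(res$peaks$indices - mid) <= 2))
})

test_that("ssf_transform matches the brute-force definition", {
  # non-increasing signal -> identically zero
  s <- sampled_signal(seq(5, 1, length.out = 50), fs = 25)
  expect_equal(ssf_transform(s, w_ssf = 0.2)$values, rep(0, 50))
  # unit-per-sample ramp with w = 4 samples -> SSF = 4 on the valid range
  r <- sampled_signal(seq_len(40), fs = 10)  # w_ssf = 0.4 -> 4 samples
  out <- ssf_transform(r, 0.4)$values
  expect_equal(out[5:40], rep(4, 36))
  expect_equal(out[1:4], rep(0, 4))
  # seeded signals against the double loop, exact equality
  for (seed in 1:5) {
    set.seed(seed)
    v <- cumsum(rnorm(200))
    s <- sampled_signal(v, fs = 25)
    w <- attr(ssf_transform(s, 0.4), "w_ssf_samples")
    expect_identical(ssf_transform(s, 0.4)$values, oracle_ssf(v, w))
  }
  expect_error(ssf_transform(s, -1), "w_ssf")
})

test_that("ssf detection recovers clean-train intervals and applies the distance rule", {
  cl <- make_clean_pulse(hr = 60, duration = 30, fs = 25, seed = 13)
  p <- ssf_detect(cl$bvp)
  expect_equal(length(p$times), length(cl$truth$times))
  ibi <- diff(p$times)
  expect_true(all(abs(ibi - 1.0) <= 2 / 25 + 1e-9))
  # non-increasing signal has no SSF peaks
  p0 <- ssf_detect(sampled_signal(seq(10, 0, length.out = 300), fs = 25))
  expect_length(p0$times, 0)
  # two candidates 0.1 s apart: only the higher survives (0.1 < 0.24)
  fs <- 50
  v <- numeric(10 * fs)
  t <- (0:(10 * fs - 1)) / fs
  v <- v + 2 * exp(-0.5 * ((t - 5.0) / 0.05)^2) + 1.5 * exp(-0.5 * ((t - 5.1) / 0.05)^2)
  p2 <- ssf_detect(sampled_signal(v, fs = fs))
  expect_lte(length(p2$times), 1)
})

test_that("local-max detection obeys its height, prominence and distance rules", {
  # strictly monotone signal: no peaks
  p <- local_max_detect(sampled_signal(seq(0, 1, length.out = 100), fs = 25))
  expect_length(p$times, 0)
  # unit sinusoid at 1 Hz: one peak per second
  fs <- 25
  t <- (0:(10 * fs - 1)) / fs
  p <- local_max_detect(sampled_signal(sin(2 * pi * t), fs = fs))
  expect_equal(length(p$times), 10)
  expect_true(all(abs(diff(p$times) - 1.0) <= 1 / fs + 1e-9))
  # a beat attenuated below the height threshold is missed
  cl <- make_clean_pulse(hr = 60, duration = 30, fs = 25, seed = 23)
  v <- cl$bvp$values
  k <- 12
  tk <- cl$truth$times[k]
  sel <- abs(signal_times(cl$bvp) - tk) < 0.45
  v[sel] <- v[sel] * 0.15
  weak <- local_max_detect(sampled_signal(v, fs = 25))
  m <- match_peaks(weak, cl$truth, search_range = 0.1)
  expect_true(tk %in% m$unmatched_truth)
  expect_equal(nrow(m$pairs), length(cl$truth$times) - 1)
})

test_that("prominence matches hand-walked cases and the exhaustive oracle", {
  v <- c(0, 3, 1, 5, 0)
  expect_equal(prominence(v, c(2, 4)), c(2, 5))
  # single triangular peak on a flat baseline: prominence = height
  tri <- c(rep(0, 10), 1:5, 4:0, rep(0, 10))
  expect_equal(prominence(tri, which.max(tri)), 5)
  expect_error(prominence(v, 3), "not a strict local maximum")
  for (seed in 1:10) {
    set.seed(seed)
    w <- cumsum(rnorm(500))
    idx <- which(diff(sign(diff(w))) == -2) + 1
    got <- prominence(w, idx)
    want <- vapply(idx, function(p) oracle_prominence(w, p), numeric(1))
    expect_identical(got, want)
  }
})

test_that("all detectors are invariant to positive rescaling", {
  for (seed in 1:10) {
    cl <- make_clean_pulse(hr = 55 + 3 * seed, duration = 20, fs = 25,
                           seed = seed, snr_db = 15)
    scaled <- cl$bvp
    scaled$values <- scaled$values * 37.5
    for (m in c("two_window", "ssf", "local_max")) {
      a <- detect_peaks(cl$bvp, m)
      b <- detect_peaks(scaled, m)
      expect_identical(a$indices, b$indices)
    }
  }
})
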