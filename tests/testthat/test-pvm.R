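test_that("covariance_pair matches the direct double-loop summation", {
  # all-zero trace
  z <- rgb_trace(matrix(0, 50, 3), fs = 25)
  cp <- covariance_pair(z, 5)
  expect_equal(cp$Cx, matrix(0, 3, 3))
  expect_equal(cp$Px_sym, matrix(0, 3, 3))
  # identical channels: every Cx entry equals the sample variance (1/N form)
  set.seed(21)
  s <- rnorm(400)
  tr <- rgb_trace(cbind(s, s, s), fs = 25)
  cp <- covariance_pair(tr, 7)
  expect_equal(cp$Cx, matrix(sum(s^2) / 400, 3, 3), tolerance = 1e-10)
  # seeded random traces against the oracle
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(240), 80, 3)
    tau <- sample(1:30, 1)
    got <- covariance_pair(rgb_trace(X, fs = 25), tau)
    want <- oracle_covariance_pair(X, tau)
    expect_equal(got$Cx, want$Cx, tolerance = 1e-12)
    expect_equal(got$Px_sym, want$Px_sym, tolerance = 1e-12)
  }
})

test_that("a sinusoid at lag = half period gives Px_sym ~ -Cx", {
  n <- 500; P <- 20
  s <- sin(2 * pi * (0:(n - 1)) / P)
  s <- s - mean(s)
  tr <- rgb_trace(cbind(s, s, s), fs = 25)
  cp <- covariance_pair(tr, P / 2)
  expect_equal(cp$Px_sym, -cp$Cx, tolerance = 2 / n * max(abs(cp$Cx)) * 10)
})

test_that("covariance_pair rejects out-of-range lags", {
  tr <- rgb_trace(matrix(rnorm(30), 10, 3), fs = 25)
  expect_error(covariance_pair(tr, 0), "tau")
  expect_error(covariance_pair(tr, 9), "tau")
})

test_that("gevd satisfies its defining constraints", {
  # identity pair and diagonal case
  g <- gevd(diag(3), diag(3))
  expect_equal(g$D, c(1, 1, 1))
  g <- gevd(diag(c(2, 1, 0.5)), diag(3))
  expect_equal(g$D, c(2, 1, 0.5))
  expect_equal(abs(g$W), diag(3), tolerance = 1e-12)
  # seeded SPD pairs: W'PxW = D (diagonal), W'CxW = I
  for (seed in 1:30) {
    set.seed(seed)
    A <- matrix(rnorm(9), 3); Cx <- crossprod(A) + 0.1 * diag(3)
    B <- matrix(rnorm(9), 3); Px <- crossprod(B) + 0.1 * diag(3)
    g <- gevd(Px, Cx)
    expect_lt(norm(t(g$W) %*% Px %*% g$W - diag(g$D), "F"), 1e-8)
    expect_lt(norm(t(g$W) %*% Cx %*% g$W - diag(3), "F"), 1e-8)
    expect_true(all(diff(g$D) <= 1e-12))
  }
  expect_error(gevd(diag(3), matrix(0, 3, 3)), "singular")
})

test_that("periodicity reaches 1 on a fully periodic mixture at its true period", {
  n <- 1000; fs <- 25; P <- 25
  t <- (0:(n - 1)) / fs
  s1 <- sin(2 * pi * t)          # period exactly P samples at 25 Hz
  s2 <- sin(4 * pi * t)
  M <- rbind(c(0.8, 0.4), c(1.0, 0.3), c(0.5, 0.9))
  X <- cbind(s1, s2) %*% t(M)
  set.seed(2)
  X <- X + 1e-6 * matrix(rnorm(3 * n), n, 3)
  X <- scale(X, scale = FALSE)
  p <- periodicity(rgb_trace(X, fs = fs), P)
  expect_equal(p$rho, 1, tolerance = 1e-3)
})

test_that("rho agrees with the direct time-domain ratio of the projection", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(150), 50, 3)
    X <- scale(X, scale = FALSE)
    tr <- rgb_trace(X, fs = 25)
    tau <- sample(2:15, 1)
    p <- periodicity(tr, tau, ridge = 0)  # unridged: exact ratio identity
    y <- as.numeric(X %*% p$w)
    expect_equal(p$rho, oracle_rho_time_domain(y, tau), tolerance = 1e-8)
  }
})

test_that("rho is invariant to channel permutation and to invertible mixing", {
  set.seed(41)
  sim <- simulate_rgb(pulse_model(mean_hr = 70), duration = 20, fs = 25,
                      corruption = corruption_model(snr_db = 10), seed = 41)
  X <- center_detrend(sim$trace)$values
  tau <- 21
  rho0 <- periodicity(rgb_trace(X, fs = 25), tau)$rho
  rho_p <- periodicity(rgb_trace(X[, c(2, 3, 1)], fs = 25), tau)$rho
  expect_equal(rho_p, rho0, tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(9), 3)
    while (abs(det(A)) < 0.3) A <- matrix(rnorm(9), 3)
    rho_m <- periodicity(rgb_trace(X %*% A, fs = 25), tau)$rho
    expect_equal(rho_m, rho0, tolerance = 1e-6)
  }
})

test_that("extract_bvp recovers the pulse period and is scale invariant", {
  sim <- simulate_rgb(pulse_model(mean_hr = 72), duration = 30, fs = 25,
                      corruption = corruption_model(snr_db = 10), seed = 17)
  tr <- center_detrend(sim$trace)
  res <- extract_bvp(tr)
  expect_lte(abs(res$tau_star - round(25 * 60 / 72)), 1)
  expect_false(res$low_periodicity)
  expect_length(res$bvp$values, nrow(tr$values))
  expect_true(res$tau_star %in% res$scan$taus)
  expect_equal(res$rho_star, max(res$scan$rhos))
  # scaling the trace by 7 changes nothing about the scan
  tr7 <- rgb_trace(7 * tr$values, fs = 25)
  res7 <- extract_bvp(tr7)
  expect_identical(res7$tau_star, res$tau_star)
  expect_equal(res7$scan$rhos, res$scan$rhos, tolerance = 1e-9)
})

test_that("pure-noise traces are flagged as low periodicity", {
  set.seed(55)
  X <- matrix(rnorm(6000), 2000, 3)
  res <- extract_bvp(rgb_trace(scale(X, scale = FALSE), fs = 25))
  expect_true(res$low_periodicity)
  expect_lt(res$rho_star, 0.3)
})

test_that("extract_bvp rejects bands the sampling rate cannot cover", {
  tr <- rgb_trace(matrix(rnorm(120), 40, 3), fs = 2)
  expect_error(extract_bvp(tr, hr_band = c(3, 4)), "fewer than 2")
})

test_that("windowed extraction matches whole-record on stationary traces", {
  sim <- simulate_rgb(pulse_model(mean_hr = 66), duration = 40, fs = 25,
                      corruption = corruption_model(snr_db = 10), seed = 91)
  tr <- center_detrend(sim$trace)
  whole <- extract_bvp(tr)
  win <- extract_bvp(tr, window_s = 15)
  expect_length(win$bvp$values, nrow(tr$values))
  expect_lte(abs(win$tau_star - whole$tau_star), 1)
})

test_that("fix_sign orients systolic peaks upward and is idempotent", {
  sim <- simulate_bvp(pulse_model(mean_hr = 60), 15, 25, no_corruption())
  v <- center_detrend(sim$signal)
  flipped <- v; flipped$values <- -flipped$values
  fixed <- fix_sign(flipped)
  sk <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_gt(sk(fixed$values), 0)
  expect_equal(fix_sign(fixed)$values, fixed$values)
  # near-symmetric sinusoid unchanged
  s <- sampled_signal(sin(2 * pi * (0:249) / 25), fs = 25)
  expect_equal(fix_sign(s)$values, s$values)
  expect_warning(fix_sign(sampled_signal(rep(1, 10), fs = 25)), "constant")
})
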