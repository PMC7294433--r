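# Independent brute-force oracles used to pin down the vectorized
# implementations. These deliberately re-derive each quantity from its
# definition with plain loops.

# covariance pair by explicit double summation
oracle_covariance_pair <- function(X, tau) {
  n <- nrow(X)
  Cx <- matrix(0, 3, 3)
  for (i in seq_len(n)) Cx <- Cx + X[i, ] %o% X[i, ]
  Cx <- Cx / n
  Px <- matrix(0, 3, 3)
  for (i in seq_len(n - tau)) Px <- Px + X[i, ] %o% X[i + tau, ]
  Px <- Px / (n - tau)
  list(Cx = Cx, Px_sym = (Px + t(Px)) / 2)
}

# time-domain periodicity ratio for a projected signal
oracle_rho_time_domain <- function(y, tau) {
  n <- length(y)
  num <- 0
  for (i in seq_len(n - tau)) num <- num + y[i] * y[i + tau]
  num / (n - tau) / (sum(y^2) / n)
}

# SSF by literal trailing-window summation
oracle_ssf <- function(v, w) {
  n <- length(v)
  dy <- numeric(n)
  for (k in 2:n) dy[k] <- max(v[k] - v[k - 1], 0)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i > w) out[i] <- sum(dy[(i - w + 1):i])
  }
  out
}

# topographic prominence by exhaustive valley search: for each side, find
# the nearest strictly higher sample and the minimum in between; a side
# with no higher terrain uses the minimum all the way to the boundary
oracle_prominence <- function(v, p) {
  n <- length(v)
  h <- v[p]
  hi_left <- which(v[seq_len(p - 1)] >= h)
  lo <- if (length(hi_left)) max(hi_left) + 1L else 1L
  left_min <- min(v[lo:(p - 1)])
  hi_right <- which(v[(p + 1):n] >= h)
  hi <- if (length(hi_right)) p + min(hi_right) - 1L else n
  right_min <- min(v[(p + 1):hi])
  h - max(left_min, right_min)
}

# optimal one-to-one peak assignment by exhaustive recursion:
# maximize matched count, then minimize total |dt| (ties broken by value)
oracle_optimal_match <- function(truth, detected, search_range) {
  best <- list(count = -1L, cost = Inf)
  nd <- length(detected)
  recurse <- function(ti, used, count, cost) {
    if (ti > length(truth)) {
      if (count > best$count || (count == best$count && cost < best$cost - 1e-12))
        best <<- list(count = count, cost = cost)
      return(invisible())
    }
    # upper bound prune
    if (count + (length(truth) - ti + 1L) < best$count) return(invisible())
    recurse(ti + 1L, used, count, cost)  # leave truth[ti] unmatched
    for (j in seq_len(nd)) {
      d <- abs(truth[ti] - detected[j])
      if (!used[j] && d <= search_range) {
        u <- used; u[j] <- TRUE
        recurse(ti + 1L, u, count + 1L, cost + d)
      }
    }
  }
  recurse(1L, logical(nd), 0L, 0)
  best
}

# beat times by an independent high-resolution phase integrator
oracle_beat_times <- function(mean_hr, rsa_freq, rsa_depth, lf_freq, lf_depth,
                              duration, grid_fs = 250) {
  T0 <- 60 / mean_hr
  f0 <- 1 / T0
  tg <- seq(0, duration, by = 1 / grid_fs)
  fi <- f0 * (1 - (rsa_depth / T0) * sin(2 * pi * rsa_freq * tg)
                - (lf_depth / T0) * sin(2 * pi * lf_freq * tg))
  ph <- c(0, cumsum((fi[-1] + fi[-length(fi)]) / 2 / grid_fs))
  stats::approx(ph, tg, xout = seq_len(floor(max(ph))))$y
}

# convenience: clean pulse-train signal with known ground truth
make_clean_pulse <- function(hr = 60, duration = 30, fs = 25, seed = 1,
                             snr_db = Inf) {
  corr <- if (is.finite(snr_db)) {
    corruption_model(snr_db = snr_db, drift_amp = 0, collapse_prob = 0)
  } else no_corruption()
  sim <- simulate_bvp(pulse_model(mean_hr = hr), duration = duration, fs = fs,
                      corruption = corr, seed = seed)
  list(bvp = fix_sign(center_detrend(sim$signal)),
       truth = peak_series(sim$truth$peak_times, source = "ground_truth"))
}
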