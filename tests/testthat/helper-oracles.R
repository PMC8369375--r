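# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

# Exhaustive two-sided Mann-Whitney p-value: enumerate all C(m+n, m)
# assignments of ranks to the first sample (tie-free data only).
enumerate_mwu_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(ix) sum(ix) - m * (m + 1) / 2)
  mu <- m * n / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exhaustive two-sided Wilcoxon signed-rank p-value: enumerate all 2^n sign
# patterns of the ranked absolute differences (tie-free, nonzero data).
enumerate_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Closed-form intersecting-tangent foot of a raised-cosine upstroke
# v(t) = (1 - cos(pi (t - t0)/tau))/2 preceded by a flat zero baseline:
# the mid-rise tangent (slope pi/(2 tau) at v = 1/2) meets v = 0 at
# t0 + tau (1/2 - 1/pi).
raised_cosine_foot <- function(t0, tau) t0 + tau * (1 / 2 - 1 / pi)

sampled_raised_cosine <- function(t0, tau, fs = 1000, total_s = 1) {
  t <- seq(0, total_s - 1 / fs, by = 1 / fs)
  v <- numeric(length(t))
  up <- t >= t0 & t <= t0 + tau
  v[up] <- (1 - cos(pi * (t[up] - t0) / tau)) / 2
  v[t > t0 + tau] <- 1
  v
}

# Dirichlet-kernel magnitude of an N-point moving average at frequency f
moving_average_gain <- function(f, N, T) {
  abs(sin(pi * f * N * T) / (N * sin(pi * f * T)))
}

# amplitude of a sinusoid estimated from the interior of a signal
interior_amplitude <- function(x, drop_frac = 0.2) {
  n <- length(x)
  keep <- x[ceiling(n * drop_frac):floor(n * (1 - drop_frac))]
  (max(keep) - min(keep)) / 2
}

# quick zero-noise simulated participant shared by several test files
cached_zero_noise_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      law <- default_law()
      sim <- simulate_session(law, zero_noise(),
                              schedule = compact_schedule(20), seed = 101,
                              lag_samples = 180)
      res <- run_participant(sim$session)
      cache <<- list(law = law, sim = sim, res = res)
    }
    cache
  }
})
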