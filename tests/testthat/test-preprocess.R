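# Filtering, R-peak detection and stream alignment.

test_that("band-pass removes DC, passes 4 Hz within 1 dB, rejects 0.2 Hz", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)

  dc <- bandpass_fir(rep(2, length(t)), fs, 1, 8)
  interior <- 3000:(length(t) - 3000)   # past the startup transient
  expect_lt(max(abs(dc[interior])), 2 * 1e-3)

  inband <- bandpass_fir(sin(2 * pi * 4 * t), fs, 1, 8)
  amp <- interior_amplitude(inband)
  expect_lt(abs(20 * log10(amp)), 1)

  stopband <- bandpass_fir(sin(2 * pi * 0.2 * t), fs, 1, 8)
  expect_lt(20 * log10(interior_amplitude(stopband)), -20)
})

test_that("band-pass is time-shift equivariant on interior samples", {
  fs <- 1000
  set.seed(2)
  x <- as.numeric(stats::filter(rnorm(8000), rep(1, 5), sides = 1))
  x[is.na(x)] <- 0
  k <- 37
  y <- bandpass_fir(x, fs, 1, 8)
  y_shift <- bandpass_fir(c(numeric(k), x[1:(length(x) - k)]), fs, 1, 8)
  i <- 3000:5000
  expect_lt(max(abs(y_shift[i + k] - y[i])), 1e-9 * max(abs(y)))
})

test_that("moving average: constants, impulse response, Dirichlet gain", {
  fs <- 1000
  expect_equal(smooth_moving_average(rep(100, 500), fs), rep(100, 500))

  x <- numeric(1000)
  x[500] <- 1
  y <- smooth_moving_average(x, fs, 50)
  expect_identical(sum(y > 0), 50L)
  expect_equal(unique(round(y[y > 0], 12)), 1 / 50)

  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  y20 <- smooth_moving_average(sin(2 * pi * 20 * t), fs, 50)
  expect_equal(interior_amplitude(y20),
               moving_average_gain(20, 50, 1 / fs), tolerance = 0.01)

  expect_error(smooth_moving_average(numeric(0), fs), "empty")
})

test_that("R peaks on a clean 60 bpm ECG come back at 1 s spacing", {
  fs <- 1000
  tpl <- make_beat_templates()
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  ecg <- numeric(length(t))
  r_true <- seq(0.5, 29.5, by = 1)
  for (r in r_true) {
    w <- which(abs(t - r) < 0.3)
    ecg[w] <- ecg[w] + tpl$ecg(t[w] - r)
  }
  rp <- detect_r_peaks(ecg, fs, raw = TRUE)
  expect_identical(length(rp), 30L)
  expect_true(all(abs(diff(rp) - 1) < 0.002))
  expect_error(detect_r_peaks(numeric(5000), fs), "no peaks")
})

test_that("R-peak detection tolerates jitter and noise", {
  sim <- simulate_session(default_law(),
                          noise_model(ecg_sd = 0.1, hr_sd = 4,
                                      burst_rate_hz = 0),
                          schedule = compact_schedule(20), seed = 12,
                          lag_samples = 0)
  fs <- 1000
  ecg <- bandpass_fir(sim$session$channels$ecg_wearable$samples, fs, 10, 40)
  rp <- detect_r_peaks(ecg, fs)
  r_true <- sim$truth$beats$r_time
  matched <- vapply(r_true, function(r) min(abs(rp - r)) <= 0.010,
                    logical(1))
  expect_gte(mean(matched), 0.99)
})

test_that("zero-noise R-peak recovery is within 2 ms for every beat", {
  run <- cached_zero_noise_run()
  fs <- 1000
  ecg <- bandpass_fir(run$sim$session$channels$ecg_wearable$samples, fs,
                      10, 40)
  rp <- detect_r_peaks(ecg, fs)
  err <- vapply(run$sim$truth$beats$r_time,
                function(r) min(abs(rp - r)), numeric(1))
  expect_lt(max(err), 0.002)
})

test_that("alignment recovers the simulated lag and is idempotent", {
  law <- default_law()
  s0 <- simulate_session(law, zero_noise(), compact_schedule(15), seed = 2,
                         lag_samples = 0)$session
  a0 <- align_to_reference(s0)
  expect_identical(a0$alignment_lag_samples, 0L)
  expect_identical(length(a0$channels$abp$samples),
                   length(s0$channels$abp$samples))

  s250 <- simulate_session(law, zero_noise(), compact_schedule(15),
                           seed = 2, lag_samples = 250)$session
  a250 <- align_to_reference(s250)
  expect_identical(a250$alignment_lag_samples, 250L)
  expect_identical(length(a250$channels$abp$samples),
                   length(s250$channels$abp$samples) - 250L)
  n <- lengths(lapply(a250$channels, `[[`, "samples"))
  expect_identical(length(unique(n)), 1L)

  twice <- align_to_reference(a250)
  expect_identical(twice$alignment_lag_samples, 0L)
})

test_that("alignment stays within one sample under channel noise", {
  law <- default_law()
  errs <- vapply(1:8, function(seed) {
    ses <- simulate_session(law,
                            noise_model(ecg_sd = 0.15, hr_sd = 4,
                                        burst_rate_hz = 0),
                            compact_schedule(15), seed = seed,
                            lag_samples = 250)$session
    abs(align_to_reference(ses)$alignment_lag_samples - 250L)
  }, numeric(1))
  expect_true(all(errs <= 1))
})
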