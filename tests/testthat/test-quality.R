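# SNR scoring, beat selection, and the fidelity gate.

mk_ensemble <- function(members, channel = "ppg_ir", fs = 1000,
                        window = 1L) {
  L <- min(lengths(members))
  members <- lapply(members, function(b) b[seq_len(L)])
  avg <- rowMeans(do.call(cbind, members))
  structure(list(channel = channel, window = window,
                 members = seq_along(members), member_beats = members,
                 avg = avg, start_time_s = 0, fs = fs, snr_db = NA_real_),
            class = "ptt_ensemble")
}

test_that("identical members hit the 60 dB cap; zero power errors", {
  beat <- sin(2 * pi * seq(0, 0.799, by = 1e-3))
  e <- mk_ensemble(replicate(10, beat, simplify = FALSE))
  expect_equal(compute_snr(e), 60)
  e0 <- mk_ensemble(replicate(3, numeric(100), simplify = FALSE))
  expect_error(compute_snr(e0), "zero-power")
  expect_error(compute_snr(mk_ensemble(list(beat))), "at least 2")
})

test_that("SNR matches the analytic expectation for white-noise members", {
  beat <- sin(2 * pi * seq(0, 0.799, by = 1e-3))
  p_tpl <- mean(beat^2)
  set.seed(21)
  for (sigma in c(0.1, 0.3)) {
    snrs <- vapply(1:100, function(i) {
      mem <- lapply(1:10, function(j) beat + rnorm(800, 0, sigma))
      compute_snr(mk_ensemble(mem))
    }, numeric(1))
    expect_lt(abs(mean(snrs) - 10 * log10(p_tpl / sigma^2)), 1.5)
  }
})

test_that("pure-noise windows score at or below -5 dB typically", {
  set.seed(22)
  snrs <- vapply(1:50, function(i) {
    mem <- lapply(1:10, function(j) rnorm(500))
    compute_snr(mk_ensemble(mem))
  }, numeric(1))
  expect_lte(median(snrs), -5)
})

test_that("SNR decreases monotonically with injected noise", {
  beat <- sin(2 * pi * seq(0, 0.799, by = 1e-3))
  set.seed(23)
  med <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(sigma) {
    median(vapply(1:20, function(i) {
      compute_snr(mk_ensemble(lapply(1:10, function(j)
        beat + rnorm(800, 0, sigma))))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

mk_ppg_like <- function(slope, snr, window) {
  # triangular beat with controlled max upstroke; snr_db injected directly
  t <- seq(0, 0.799, by = 1e-3)
  up <- pmin((t - 0.2) * slope, 0.3 * slope)
  up[t < 0.2] <- 0
  e <- mk_ensemble(list(up, up), window = window)
  e$snr_db <- snr
  e
}

test_that("PPG selection: top-decile upstroke pool, then max SNR, ties early", {
  slopes <- c(1.0, 0.9, rep(0.5, 18))
  snrs <- c(5, 12, rep(30, 18))
  ens <- lapply(seq_along(slopes), function(i)
    mk_ppg_like(slopes[i], snrs[i], i))
  expect_identical(select_ppg_ensemble(ens), 2L)  # pool {A, B}, B wins on SNR

  ens5 <- lapply(1:5, function(i) mk_ppg_like(c(2, 1, 1, 1, 1)[i],
                                              c(0, 40, 40, 40, 40)[i], i))
  expect_identical(select_ppg_ensemble(ens5), 1L)  # pool of 1: SNR ignored

  both <- lapply(1:20, function(i) mk_ppg_like(ifelse(i == 7, 2, 1),
                                               ifelse(i == 7, 50, 10), i))
  expect_identical(select_ppg_ensemble(both), 7L)
  expect_error(select_ppg_ensemble(list()), "empty")
})

test_that("PPG selection never leaves the top-decile upstroke pool", {
  set.seed(31)
  for (rep in 1:30) {
    m <- sample(3:40, 1)
    ens <- lapply(seq_len(m), function(i)
      mk_ppg_like(runif(1, 0.5, 2), runif(1, -5, 40), i))
    up <- vapply(ens, function(e) max(diff(e$avg)) * e$fs, numeric(1))
    pool <- order(-up)[seq_len(max(1, ceiling(0.1 * m)))]
    expect_true(select_ppg_ensemble(ens) %in% pool)
  }
})

test_that("reference-beat selection takes the max-SNR window, ties early", {
  mk_abp <- function(snr, window) {
    e <- mk_ensemble(list(rep(100, 800), rep(100, 800)), channel = "abp",
                     window = window)
    e$snr_db <- snr
    e
  }
  ens <- lapply(seq_along(c(10, 30, 20)), function(i)
    mk_abp(c(10, 30, 20)[i], i))
  expect_identical(select_reference_bp(ens), 2L)
  expect_identical(select_reference_bp(ens[1]), 1L)
  expect_identical(select_reference_bp(lapply(1:3, mk_abp, snr = 15)), 1L)
})

test_that("fidelity gate: pass case, per-channel failures, foot range", {
  thr <- c(scg = 10, ppg = 10, abp = 20)
  ok <- gate_task(c(scg = 15, ppg = 12, abp = 25), thr, pat_s = 0.21)
  expect_true(ok$kept)
  expect_length(ok$reasons, 0)

  g <- gate_task(c(scg = 8, ppg = 12, abp = 25), thr, pat_s = 0.21)
  expect_false(g$kept)
  expect_identical(g$reasons, "scg_snr")

  g <- gate_task(c(scg = 15, ppg = 12, abp = 25), thr, pat_s = 0.02)
  expect_identical(g$reasons, "foot_range")

  g <- gate_task(c(scg = 15, ppg = 12, abp = 25), thr, pat_s = 0.21,
                 ao_found = FALSE)
  expect_identical(g$reasons, "no_ao")
})

test_that("raising thresholds never converts a dropped task to kept", {
  set.seed(33)
  for (i in 1:50) {
    snr <- c(scg = runif(1, 0, 30), ppg = runif(1, 0, 30),
             abp = runif(1, 0, 30))
    thr1 <- c(scg = runif(1, 0, 30), ppg = runif(1, 0, 30),
              abp = runif(1, 0, 30))
    bump <- runif(3, 0, 10)
    thr2 <- thr1 + bump
    pat <- runif(1, 0.05, 0.55)
    g1 <- gate_task(snr, thr1, pat)
    g2 <- gate_task(snr, thr2, pat)
    expect_true(g1$kept || !g2$kept)
  }
})

test_that("default participant thresholds sit just below the 25th percentile", {
  s <- list(ppg = c(10, 20, 30, 40), scg = rep(60, 4), abp = 1:4)
  thr <- snr_thresholds(s)
  expect_lt(thr[["ppg"]], quantile(s$ppg, 0.25))
  expect_gt(thr[["scg"]], 60 - 1e-3)  # all-equal pools stay passable
  expect_true(60 > thr[["scg"]])
})
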