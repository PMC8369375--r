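# Preprocessing: FIR band-pass filtering with group-delay compensation,
# moving-average smoothing, R-peak detection, and cross-correlation
# alignment of the wearable and reference streams.

#' Default filter band table
#'
#' Band-pass edges per modality: ECG 10-40 Hz (R-wave extraction, baseline
#' wander removal), SCG 1-40 Hz, PPG 1-8 Hz, and a 50 ms moving average for
#' the continuous arterial pressure.
#'
#' @return data.frame with columns `channel`, `kind`, `f_lo`, `f_hi`,
#'   `window_ms`.
#' @export
filter_bands <- function() {
  data.frame(
    channel = c("ecg_wearable", "ecg_ref", "scg_z", "ppg_green", "ppg_red",
                "ppg_ir", "abp"),
    kind = c(rep("bandpass", 6), "moving_average"),
    f_lo = c(10, 10, 1, 1, 1, 1, NA),
    f_hi = c(40, 40, 40, 8, 8, 8, NA),
    window_ms = c(rep(NA, 6), 50),
    stringsAsFactors = FALSE)
}

fir_order <- function(fs, f_lo, cap = 2000) {
  o <- min(round(4 * fs / f_lo / 2) * 2, cap)
  as.integer(o)
}

#' Linear-phase FIR band-pass filter with delay compensation
#'
#' Windowed-sinc (Hamming) band-pass applied via FFT convolution; the known
#' group delay (order/2 samples) is removed so fiducial timings are
#' unbiased. Output has the same length as the input; samples within half
#' the filter length of either edge carry the usual startup transient.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param f_lo,f_hi Band edges, `0 < f_lo < f_hi < fs/2`.
#' @param order Filter order (even); default `min(4 fs / f_lo, 2000)`.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_fir <- function(x, fs, f_lo, f_hi, order = NULL) {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2)) {
    stop("invalid band: need 0 < f_lo < f_hi < fs/2")
  }
  if (is.null(order)) order <- fir_order(fs, f_lo)
  if (length(x) <= order) stop("signal shorter than filter order")
  b <- signal::fir1(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  b <- b - mean(b)   # exact DC null (windowed design leaves ~-54 dB at 0 Hz)
  d <- order / 2
  y <- signal::fftfilt(b, c(x, numeric(d)))
  y[(d + 1):(d + length(x))]
}

#' Centered moving-average smoother
#'
#' Window of `round(window_ms * fs / 1000)` samples; edges use shrinking
#' windows (the mean over whatever part of the window overlaps the signal).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_ms Window length in milliseconds (>= one sample).
#' @return Smoothed signal, same length as `x`.
#' @export
smooth_moving_average <- function(x, fs, window_ms = 50) {
  if (!length(x)) stop("empty signal")
  w <- max(1L, round(window_ms * fs / 1000))
  n <- length(x)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect ECG R peaks
#'
#' Simple amplitude-based detector: local maxima above half the rolling
#' 2-second maximum, with a refractory period. Intended to run on the
#' 10-40 Hz band-passed ECG; set `raw = TRUE` to apply the band-pass first.
#'
#' @param ecg Numeric ECG signal.
#' @param fs Sampling rate (Hz).
#' @param raw If `TRUE`, band-pass 10-40 Hz before detection.
#' @param refractory_s Minimum separation between peaks (default 0.25 s,
#'   supporting rates up to 240 bpm).
#' @return Strictly increasing R-peak times in seconds (sample resolution;
#'   time 0 is sample 1).
#' @export
detect_r_peaks <- function(ecg, fs, raw = FALSE, refractory_s = 0.25) {
  if (raw) ecg <- bandpass_fir(ecg, fs, 10, 40)
  n <- length(ecg)
  if (n < 3) stop("no peaks found: signal too short")
  # rolling 2 s maximum, approximated block-wise (1 s blocks, max over the
  # block and its neighbours)
  bs <- as.integer(fs)
  nb <- ceiling(n / bs)
  pad <- c(ecg, rep(-Inf, nb * bs - n))
  bmax <- apply(matrix(pad, nrow = bs), 2, max)
  roll <- pmax(bmax,
               c(bmax[1], bmax[-nb]),
               c(bmax[-1], bmax[nb]))
  thr <- 0.5 * roll
  cand <- which(diff(sign(diff(ecg))) < 0) + 1L
  cand <- cand[ecg[cand] > thr[pmin((cand - 1L) %/% bs + 1L, nb)]]
  if (!length(cand)) stop("no peaks found")
  refr <- round(refractory_s * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (ecg[i] > ecg[last]) {
      keep[length(keep)] <- i   # replace weaker peak inside refractory span
      last <- i
    }
  }
  (keep - 1L) / fs
}

# Cross-correlation of two R-peak impulse trains over integer lags in
# [-max_lag, max_lag] samples, computed by tabulating pairwise differences.
rpeak_xcorr_lag <- function(r_wear_s, r_ref_s, fs, max_lag_s = 0.4) {
  a <- round(r_wear_s * fs)
  b <- round(r_ref_s * fs)
  d <- outer(b, a, "-")
  d <- d[abs(d) <= round(max_lag_s * fs)]
  if (!length(d)) stop("no R-peak pairs within the alignment search window")
  lags <- sort(unique(d))
  counts <- tabulate(match(d, lags))
  # triangular smoothing over +/-1 sample absorbs detector jitter
  sm <- counts
  for (k in seq_along(lags)) {
    nb <- which(abs(lags - lags[k]) == 1L)
    sm[k] <- counts[k] + 0.5 * sum(counts[nb])
  }
  best <- which.max(sm)
  away <- abs(lags - lags[best]) > 2L
  if (any(away) && max(sm[away]) > 0.99 * sm[best]) {
    stop("ambiguous alignment: two cross-correlation lags within 1% of the ",
         "maximum")
  }
  lags[best]
}

#' Align wearable and reference streams by their ECG R-peaks
#'
#' Detects R peaks in both ECGs, finds the lag maximizing the
#' cross-correlation of the two R-peak impulse trains, shifts the lagging
#' group and truncates both groups to common support. Applying the
#' operation twice is the identity (second lag is 0).
#'
#' @param session A `ptt_session` with both ECG channels.
#' @param max_lag_s Alignment search half-window in seconds. Must exceed
#'   the acquisition offset but stay below one R-R interval, otherwise the
#'   rhythm's own periodicity makes the cross-correlation ambiguous.
#' @return The aligned session with `alignment_lag_samples` set (positive:
#'   reference stream lagged the wearable stream).
#' @export
align_to_reference <- function(session, max_lag_s = 0.4) {
  fs <- session$channels[["ecg_wearable"]]$fs
  rw <- detect_r_peaks(bandpass_fir(session$channels[["ecg_wearable"]]$samples,
                                    fs, 10, 40), fs)
  rr <- detect_r_peaks(bandpass_fir(session$channels[["ecg_ref"]]$samples,
                                    fs, 10, 40), fs)
  if (length(rw) < 5 || length(rr) < 5) {
    stop("need at least 5 R peaks in each ECG to align")
  }
  lag <- rpeak_xcorr_lag(rw, rr, fs, max_lag_s)
  ref <- reference_channel_roles()
  chans <- session$channels
  if (lag != 0L) {
    for (nm in names(chans)) {
      x <- chans[[nm]]$samples
      if (nm %in% ref) {
        if (lag > 0L) x <- x[(lag + 1L):length(x)]
      } else {
        if (lag < 0L) x <- x[(-lag + 1L):length(x)]
      }
      chans[[nm]]$samples <- x
    }
  }
  ncommon <- min(lengths(lapply(chans, `[[`, "samples")))
  for (nm in names(chans)) {
    chans[[nm]]$samples <- chans[[nm]]$samples[seq_len(ncommon)]
  }
  out <- session
  out$channels <- chans
  dur <- ncommon / fs
  out$annotations$end_s <- pmin(out$annotations$end_s, dur)
  out$annotations <- out$annotations[out$annotations$start_s < dur, ]
  out$alignment_lag_samples <- as.integer(lag)
  out
}
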