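# Window-level SNR scoring, the PPG selection rule (top-decile upstrokes,
# then maximum SNR), reference-beat selection, and the task fidelity gate.

SNR_CAP_DB <- 60

#' Signal-to-noise ratio of an ensemble window
#'
#' `SNR_dB = 10 log10(P_signal / P_noise)` with `P_signal` the mean power
#' of the ensemble-averaged beat and `P_noise` the mean power of the member
#' residuals about the average, capped at +60 dB (identical members have
#' zero residual). This is a self-contained surrogate for the external
#' noise-detection algorithm the processing chain is built around, and can
#' be swapped via the `snr_fun` entry of [run_config()].
#'
#' @param ensemble A `ptt_ensemble` (>= 2 member beats), or a list of
#'   member beats when `avg` is supplied separately.
#' @param avg Averaged beat (optional when `ensemble` is a `ptt_ensemble`).
#' @return SNR in dB.
#' @export
compute_snr <- function(ensemble, avg = NULL) {
  if (inherits(ensemble, "ptt_ensemble")) {
    members <- ensemble$member_beats
    avg <- ensemble$avg
  } else {
    members <- ensemble
  }
  if (length(members) < 2) stop("need at least 2 member beats")
  L <- min(lengths(members), length(avg))
  a <- avg[seq_len(L)]
  p_sig <- mean(a^2)
  p_noise <- mean(vapply(members,
                         function(b) mean((b[seq_len(L)] - a)^2),
                         numeric(1)))
  if (p_sig == 0 && p_noise == 0) stop("zero-power window")
  if (p_noise == 0) return(SNR_CAP_DB)
  min(10 * log10(p_sig / p_noise), SNR_CAP_DB)
}

# attach SNR to each ensemble in a list
score_ensembles <- function(ensembles, snr_fun = compute_snr) {
  lapply(ensembles, function(e) {
    e$snr_db <- snr_fun(e)
    e
  })
}

max_upstroke <- function(e) max(diff(e$avg)) * e$fs

#' Select the optimal PPG ensemble of a task
#'
#' The physiologically motivated rule: restrict to the candidates with the
#' top 10% of systolic upstrokes (maximum first derivative of the averaged
#' waveform; pool size `ceiling(0.1 M)`, at least 1), then pick the pool
#' member with the largest SNR. Ties go to the earlier window.
#'
#' @param ensembles Non-empty list of PPG `ptt_ensemble`s with `snr_db` set.
#' @param top_frac Upstroke pool fraction (default 0.1).
#' @return Index of the chosen ensemble within `ensembles`.
#' @export
select_ppg_ensemble <- function(ensembles, top_frac = 0.1) {
  m <- length(ensembles)
  if (!m) stop("empty ensemble list")
  up <- vapply(ensembles, max_upstroke, numeric(1))
  pool_n <- max(1L, ceiling(top_frac * m))
  pool <- order(-up)[seq_len(pool_n)]   # order() breaks ties by index
  snr <- vapply(ensembles[pool], `[[`, numeric(1), "snr_db")
  pool[which.max(snr)]   # which.max ties -> first (earlier window)
}

#' Select the reference pressure ensemble of a task
#'
#' The arterial-pressure beat with the highest SNR; ties go to the earlier
#' window.
#'
#' @param ensembles Non-empty list of ABP `ptt_ensemble`s with `snr_db` set.
#' @return Index of the chosen ensemble.
#' @export
select_reference_bp <- function(ensembles) {
  if (!length(ensembles)) stop("empty ensemble list")
  which.max(vapply(ensembles, `[[`, numeric(1), "snr_db"))
}

#' Participant-specific SNR thresholds
#'
#' Default gating thresholds: the 25th percentile of the participant's
#' per-channel window SNRs, nudged down by 1e-6 dB so windows sitting
#' exactly at the percentile (e.g. every window of a clean recording)
#' survive the strict `>` gate.
#'
#' @param snr_by_channel Named list mapping channel label to the numeric
#'   vector of that participant's window SNRs.
#' @param probs Quantile used (default 0.25).
#' @return Named numeric vector of thresholds (dB).
#' @export
snr_thresholds <- function(snr_by_channel, probs = 0.25) {
  vapply(snr_by_channel,
         function(s) stats::quantile(s, probs, names = FALSE) - 1e-6,
         numeric(1))
}

#' Gate a task selection on fidelity
#'
#' A task is kept only if the SNRs of the selected SCG, PPG and ABP
#' ensembles all strictly exceed their thresholds and the PPG foot (as a
#' pulse arrival time from the R peak) lies within the configured realistic
#' range. Dropped tasks carry machine-readable reasons (`"scg_snr"`,
#' `"ppg_snr"`, `"abp_snr"`, `"foot_range"`, `"no_ao"`).
#'
#' @param snr Named numeric vector `c(scg=, ppg=, abp=)` of selected-beat
#'   SNRs (dB); `NA` entries are treated as failures.
#' @param thresholds Named numeric vector of cutoffs for the same channels.
#' @param pat_s PPG foot time relative to the R peak (s), or `NA`.
#' @param foot_range_s Allowed `[lo, hi]` pulse-arrival range (default
#'   0.10-0.50 s).
#' @param ao_found Whether a qualifying aortic-valve-opening peak exists.
#' @return List with `kept` (logical) and `reasons` (character vector,
#'   empty when kept).
#' @export
gate_task <- function(snr, thresholds, pat_s,
                      foot_range_s = c(0.10, 0.50), ao_found = TRUE) {
  reasons <- character()
  for (ch in c("scg", "ppg", "abp")) {
    if (is.na(snr[[ch]]) || !(snr[[ch]] > thresholds[[ch]])) {
      reasons <- c(reasons, paste0(ch, "_snr"))
    }
  }
  if (is.na(pat_s) || pat_s < foot_range_s[1] || pat_s > foot_range_s[2]) {
    reasons <- c(reasons, "foot_range")
  }
  if (!isTRUE(ao_found)) reasons <- c(reasons, "no_ao")
  list(kept = !length(reasons), reasons = reasons)
}
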