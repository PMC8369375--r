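# Heartbeat segmentation on R-R boundaries and ensemble averaging in
# overlapping windows.

#' Segment a signal into heartbeats on R-R boundaries
#'
#' Beat i spans the half-open sample range `[R_i, R_(i+1))`; the beats
#' partition the signal between the first and last R peak with no gaps or
#' overlaps.
#'
#' @param x Numeric signal.
#' @param r_times R-peak times in seconds (>= 2, strictly increasing).
#' @param fs Sampling rate (Hz).
#' @param channel Channel label carried along for provenance.
#' @return A `ptt_beatset`: list with `channel`, `fs`, `r_times`,
#'   `start_time_s` (one per beat) and `beats` (list of numeric vectors).
#' @export
segment_heartbeats <- function(x, r_times, fs, channel = "") {
  if (length(r_times) < 2) stop("need at least 2 R times to segment beats")
  if (is.unsorted(r_times, strictly = TRUE)) {
    stop("r_times must be strictly increasing")
  }
  idx <- round(r_times * fs) + 1L
  if (idx[1] < 1L || idx[length(idx)] - 1L > length(x)) {
    stop("R times outside the signal")
  }
  nb <- length(idx) - 1L
  beats <- vector("list", nb)
  for (i in seq_len(nb)) beats[[i]] <- x[idx[i]:(idx[i + 1L] - 1L)]
  structure(list(channel = channel, fs = fs, r_times = r_times,
                 start_time_s = r_times[seq_len(nb)], beats = beats),
            class = "ptt_beatset")
}

#' Ensemble-average beats in overlapping windows
#'
#' Window k covers `width` consecutive beats starting at beat
#' `(k-1) * hop + 1`; with the defaults (width 10, hop 5) windows overlap by
#' 50%. Members are aligned at their R-anchored start and averaged over the
#' common (shortest-member) length; trailing beats that do not fill a final
#' window are dropped. The number of windows is
#' `floor((N - width)/hop) + 1`.
#'
#' @param beatset A [segment_heartbeats()] result.
#' @param width Beats per window.
#' @param hop Window hop in beats.
#' @return List of `ptt_ensemble` objects: `channel`, `window`, `members`
#'   (beat indices), `avg` (averaged samples), `start_time_s`, `fs`,
#'   `snr_db` (`NA` until [compute_snr()] is applied).
#' @export
ensemble_windows <- function(beatset, width = 10, hop = 5) {
  nb <- length(beatset$beats)
  if (nb < width) {
    stop(sprintf("need at least %d beats for one ensemble window (have %d)",
                 width, nb))
  }
  nw <- (nb - width) %/% hop + 1L
  lapply(seq_len(nw), function(k) {
    members <- ((k - 1L) * hop + 1L):((k - 1L) * hop + width)
    mb <- beatset$beats[members]
    L <- min(lengths(mb))
    avg <- rowMeans(vapply(mb, function(b) b[seq_len(L)], numeric(L)))
    structure(list(channel = beatset$channel, window = k, members = members,
                   member_beats = lapply(mb, function(b) b[seq_len(L)]),
                   avg = avg,
                   start_time_s = beatset$start_time_s[members[1]],
                   fs = beatset$fs, snr_db = NA_real_),
              class = "ptt_ensemble")
  })
}

#' Read reference pressures off an ABP ensemble beat
#'
#' SBP is the maximum, DBP the minimum and MAP the time average of the
#' ensemble-averaged arterial pressure beat.
#'
#' @param ensemble A `ptt_ensemble` from the `abp` channel.
#' @return Named numeric vector `c(SBP=, DBP=, MAP=)` in mm Hg, satisfying
#'   DBP <= MAP <= SBP.
#' @export
abp_beat_bp <- function(ensemble) {
  if (!identical(ensemble$channel, "abp")) {
    stop("abp_beat_bp expects an ensemble from the abp channel, got: ",
         ensemble$channel)
  }
  x <- ensemble$avg
  c(SBP = max(x), DBP = min(x), MAP = mean(x))
}
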