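# Fiducial detection: PPG diastolic foot by intersecting tangents, SCG
# aortic-valve-opening (AO) peak, and the transit time between them.

#' PPG diastolic foot by the intersecting-tangent method
#'
#' The foot is the abscissa of the intersection between (a) the tangent to
#' the systolic upstroke at its point of maximum first derivative (centered
#' difference) and (b) the horizontal line through the local minimum
#' preceding the upstroke. The intersection is computed by exact line
#' algebra, so the result is sub-sample.
#'
#' @param beat Numeric ensemble-averaged PPG beat (R-anchored; time 0 is
#'   the first sample).
#' @param fs Sampling rate (Hz).
#' @return Foot time in seconds from beat start.
#' @export
ppg_foot_intersecting_tangent <- function(beat, fs) {
  n <- length(beat)
  if (n < 5) stop("beat too short for foot detection")
  d <- (beat[3:n] - beat[1:(n - 2)]) * fs / 2   # centered difference
  im <- which.max(d) + 1L                       # index into beat
  if (im <= 2L || im >= n - 1L) {
    stop("derivative maximum at beat boundary; no usable rising edge")
  }
  slope <- d[im - 1L]
  if (slope <= 0) stop("no rising edge found")
  # walk back to the local minimum preceding the upstroke
  j <- im
  while (j > 1L && beat[j - 1L] <= beat[j]) j <- j - 1L
  if (j == im) stop("no preceding local minimum; upstroke at beat start")
  v_min <- beat[j]
  t_m <- (im - 1L) / fs
  t_m - (beat[im] - v_min) / slope
}

#' Detect the SCG aortic-valve-opening point
#'
#' AO is taken as the earliest local maximum of the ensemble-averaged SCG
#' beat whose latency lies inside the pre-ejection-period constraint window
#' and before the PPG foot, with prominence above a floor (fraction of the
#' beat's peak-to-peak amplitude). Peak latency is refined to sub-sample
#' precision with a three-point parabola.
#'
#' @param scg_beat Numeric ensemble-averaged SCG beat (R-anchored).
#' @param fs Sampling rate (Hz).
#' @param foot_time_s PPG foot time of the paired beat (s from beat start).
#' @param pep_range_s Allowed AO latency window `[lo, hi]` in seconds
#'   (default 0.03-0.15), intersected with `[0, foot_time_s)`.
#' @param prominence_frac Prominence floor as a fraction of beat
#'   peak-to-peak (default 0.1).
#' @param all_candidates Return every qualifying peak instead of the first.
#' @return AO time in seconds, or (with `all_candidates = TRUE`) a numeric
#'   vector of candidate times. Errors if no peak qualifies.
#' @export
detect_ao <- function(scg_beat, fs, foot_time_s,
                      pep_range_s = c(0.03, 0.15), prominence_frac = 0.1,
                      all_candidates = FALSE) {
  hi <- min(pep_range_s[2], foot_time_s)
  if (!(pep_range_s[1] < hi)) {
    stop("no qualifying AO peak: constraint window is empty")
  }
  p2p <- diff(range(scg_beat))
  if (p2p <= 0) stop("no qualifying AO peak: flat beat")
  pk_idx <- local_maxima(scg_beat)
  pk_idx <- pk_idx[peak_prominence(scg_beat, pk_idx) >=
                     prominence_frac * p2p]
  if (!length(pk_idx)) {
    stop("no qualifying AO peak found before the PPG foot")
  }
  t_pk <- (pk_idx - 1) / fs
  ok <- t_pk >= pep_range_s[1] & t_pk < hi
  if (!any(ok)) stop("no qualifying AO peak found before the PPG foot")
  refine <- function(i) {
    if (i <= 1L || i >= length(scg_beat)) return((i - 1) / fs)
    y0 <- scg_beat[i - 1L]; y1 <- scg_beat[i]; y2 <- scg_beat[i + 1L]
    den <- y0 - 2 * y1 + y2
    off <- if (den < 0) 0.5 * (y0 - y2) / den else 0
    (i - 1 + max(-0.5, min(0.5, off))) / fs
  }
  cand_idx <- pk_idx[ok]
  cand <- sort(vapply(cand_idx, refine, numeric(1)))
  if (all_candidates) cand else cand[1]
}

# interior local maxima (strict on the left, non-strict on the right so
# plateau onsets count once)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# topographic prominence: drop from the peak to the highest saddle
# separating it from higher terrain on either side
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > h)
    min_l <- if (length(higher_l)) {
      min(left[(max(higher_l) + 1L):(i - 1L)])
    } else if (length(left)) min(left) else h
    right <- x[seq((i + 1L), length(x))]
    higher_r <- which(right > h)
    min_r <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r) - 1L)])
    } else if (length(right)) min(right) else h
    h - max(min_l, min_r)
  }, numeric(1))
}

#' Pulse transit time from the two fiducials
#'
#' @param ao_time_s Aortic-valve-opening time (s from beat start).
#' @param foot_time_s PPG foot time (s from beat start).
#' @return `foot_time_s - ao_time_s` in seconds (must be positive).
#' @export
compute_ptt <- function(ao_time_s, foot_time_s) {
  ptt <- foot_time_s - ao_time_s
  if (!is.finite(ptt) || ptt <= 0) {
    stop("non-positive transit time: AO must precede the PPG foot")
  }
  ptt
}
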