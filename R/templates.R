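# Beat-level waveform templates used by the simulator. Morphologies are
# stylized: each template is built so that its ground-truth fiducial is
# geometrically exact (the PPG upstroke is locally linear at the foot, the
# SCG first positive peak sits exactly at the requested AO offset, the ABP
# beat has analytic min/max/mean), which is what makes the generator a
# usable oracle for the detectors downstream.

#' Template configuration for the beat simulator
#'
#' @param ecg_r_amp,ecg_r_sigma_s Gaussian R-wave amplitude and width (s).
#' @param ecg_t_amp,ecg_t_sigma_s,ecg_t_offset_s Low-frequency T-wave bump
#'   (removed by the 10-40 Hz ECG band-pass; present so the detector is
#'   exercised on more than a bare spike).
#' @param scg_freq_hz,scg_sigma_s Carrier frequency and Gaussian envelope
#'   SD of the seismocardiogram burst. The envelope keeps the burst's
#'   spectrum inside the 1-40 Hz measurement band, so band-pass filtering
#'   leaves the peak (the aortic-valve-opening marker, exactly at the
#'   envelope centre) in place.
#' @param ppg_sigma_cycles Width (in fractions of a beat) of the wrapped
#'   Gaussian whose heart-rate harmonics 2-6 synthesize the PPG beat. With
#'   no energy at DC or the heart-rate fundamental, the beat passes the
#'   1-8 Hz measurement band essentially undistorted; the second harmonic
#'   produces a physiological secondary (dicrotic-like) wave in diastole.
#'   The template is time-registered so that its intersecting-tangent foot
#'   falls exactly at the requested foot time.
#' @param abp_rise_s,abp_fall_s ABP systolic upstroke and downstroke
#'   durations (s); the systolic plateau length is solved per beat so the
#'   beat's time average equals the task MAP exactly.
#' @return A named list of template parameters.
#' @export
template_config <- function(ecg_r_amp = 1, ecg_r_sigma_s = 0.008,
                            ecg_t_amp = 0.15, ecg_t_sigma_s = 0.04,
                            ecg_t_offset_s = 0.25,
                            scg_freq_hz = 20, scg_sigma_s = 0.02,
                            ppg_sigma_cycles = 0.13,
                            abp_rise_s = 0.06, abp_fall_s = 0.15) {
  as.list(environment())
}

# Fourier coefficients of a wrapped Gaussian of width sigma (cycles),
# harmonics 2..6 only
ppg_harmonic_coefs <- function(sigma) {
  k <- 2:6
  list(k = k, a = exp(-2 * (pi * k * sigma)^2))
}

# Shape properties of the harmonic PPG for one beat length: location of
# the intersecting-tangent foot relative to the pulse centre, plus the
# global min/max for unit normalization. Solved once per beat length.
ppg_shape_props <- function(beat_len, sigma) {
  hc <- ppg_harmonic_coefs(sigma)
  w <- 2 * pi / beat_len
  v <- function(t) drop(cos(outer(t, hc$k) * w) %*% hc$a)
  dv <- function(t) drop(-sin(outer(t, hc$k) * w) %*% (hc$a * hc$k * w))
  up <- stats::optimize(dv, c(-0.35 * beat_len, 0), maximum = TRUE,
                        tol = 1e-10)
  t_ms <- up$maximum
  lo <- stats::optimize(v, c(-0.45 * beat_len, t_ms), tol = 1e-10)
  foot_off <- t_ms - (v(t_ms) - lo$objective) / up$objective
  list(foot_off = foot_off, vmin = lo$objective, vmax = sum(hc$a))
}

#' Beat templates for the four simulated modalities
#'
#' Returns evaluable waveform functions of continuous time. ECG and SCG
#' templates are additive (zero-baseline, placed at each R time); PPG and
#' ABP templates tile one beat `[0, beat_len)` and take the beat's fiducial
#' and pressure parameters as arguments.
#'
#' @param config A [template_config()].
#' @return List with functions `ecg(t)`, `scg(t, ao_s)`,
#'   `ppg(t, beat_len, foot_s)` and `abp(t, beat_len, dbp, sbp, map, foot_s)`.
#'   `scg`'s first prominent positive peak falls at `ao_s`; `ppg`'s
#'   intersecting-tangent foot at `foot_s`; `abp` attains min `dbp`,
#'   max `sbp` and time-average `map` over the beat.
#' @export
make_beat_templates <- function(config = template_config()) {
  cf <- config

  ecg <- function(t) {
    cf$ecg_r_amp * exp(-t^2 / (2 * cf$ecg_r_sigma_s^2)) +
      cf$ecg_t_amp *
        exp(-(t - cf$ecg_t_offset_s)^2 / (2 * cf$ecg_t_sigma_s^2))
  }

  scg <- function(t, ao_s) {
    x <- t - ao_s
    exp(-x^2 / (2 * cf$scg_sigma_s^2)) * cos(2 * pi * cf$scg_freq_hz * x)
  }

  shape_memo <- new.env(parent = emptyenv())
  ppg <- function(t, beat_len, foot_s) {
    if (foot_s >= beat_len) {
      stop("PPG template does not fit: foot time exceeds beat length")
    }
    key <- sprintf("%.6f", beat_len)
    props <- shape_memo[[key]]
    if (is.null(props)) {
      props <- ppg_shape_props(beat_len, cf$ppg_sigma_cycles)
      shape_memo[[key]] <- props
    }
    hc <- ppg_harmonic_coefs(cf$ppg_sigma_cycles)
    t_c <- foot_s - props$foot_off
    w <- 2 * pi / beat_len
    v <- drop(cos(outer(t - t_c, hc$k) * w) %*% hc$a)
    (v - props$vmin) / (props$vmax - props$vmin)
  }

  abp <- function(t, beat_len, dbp, sbp, map, foot_s) {
    pp <- sbp - dbp
    if (pp <= 0 || map <= dbp || map >= sbp) {
      stop("ABP template requires dbp < map < sbp")
    }
    rise <- cf$abp_rise_s
    # area above dbp (in seconds, relative to pp) required for the beat
    # time-average to equal map exactly
    a <- (map - dbp) * beat_len / pp
    room <- beat_len - 0.02 - foot_s - rise
    # plateau + fall must carry area a - rise/2 and fit inside `room`;
    # shorten the downstroke on short beats before giving up
    fall <- min(cf$abp_fall_s, 2 * (room - a + rise / 2))
    plateau <- a - rise / 2 - fall / 2
    if (fall < 0.03 || plateau < 0.02 || plateau + fall > room) {
      stop("ABP template does not fit within the beat; beat too short for ",
           "the requested pressures")
    }
    out <- rep(dbp, length(t))
    x <- t - foot_s
    up <- x >= 0 & x < rise
    out[up] <- dbp + pp * (1 - cos(pi * x[up] / rise)) / 2
    fl <- x >= rise & x < rise + plateau
    out[fl] <- sbp
    dn <- x >= rise + plateau & x < rise + plateau + fall
    out[dn] <- dbp + pp * (1 + cos(pi * (x[dn] - rise - plateau) / fall)) / 2
    out
  }

  list(ecg = ecg, scg = scg, ppg = ppg, abp = abp, config = cf)
}
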