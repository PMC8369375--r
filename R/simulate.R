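# Synthetic multichannel sessions with known ground truth.

#' Channel noise model
#'
#' Additive white noise per channel, Poisson-timed motion-artifact bursts of
#' band-limited noise, wavelength-dependent PPG amplitude scaling (the
#' downstream effect of melanin/BMI on optical SNR: infrared largest, green
#' smallest), and heart-rate variability for the R-R jitter.
#'
#' @param ecg_sd,scg_sd,ppg_sd,abp_sd Additive white noise SD per channel,
#'   in each channel's physical units. The PPG SD is shared across
#'   wavelengths, so the amplitude scale alone sets the SNR ordering.
#' @param burst_rate_hz Rate of motion-artifact bursts (events/s).
#' @param burst_amp_mult Burst amplitude as a multiple of the channel SD.
#' @param burst_dur_s Length-2 range of burst durations (s).
#' @param ppg_amp_scale Named multiplier in (0, 1] per PPG channel.
#' @param hr_mean,hr_sd Heart rate mean and SD (bpm) driving R-R jitter.
#' @return An object of class `ptt_noise`.
#' @export
noise_model <- function(ecg_sd = 0.05, scg_sd = 0.05, ppg_sd = 0.03,
                        abp_sd = 1, burst_rate_hz = 1 / 60,
                        burst_amp_mult = 10, burst_dur_s = c(0.5, 2),
                        ppg_amp_scale = c(ppg_green = 0.4, ppg_red = 0.7,
                                          ppg_ir = 1.0),
                        hr_mean = 70, hr_sd = 3) {
  stopifnot(ecg_sd >= 0, scg_sd >= 0, ppg_sd >= 0, abp_sd >= 0,
            burst_rate_hz >= 0, hr_mean > 30, hr_sd >= 0,
            all(ppg_amp_scale > 0), all(ppg_amp_scale <= 1))
  structure(as.list(environment()), class = "ptt_noise")
}

#' Noise-free study condition
#'
#' All additive noise, motion bursts and R-R jitter switched off: every
#' beat is an exact copy of the template, so the pipeline's recovery of the
#' ground-truth law is limited only by sampling and filtering.
#'
#' @inheritParams noise_model
#' @return A `ptt_noise` with all stochastic terms zero.
#' @export
zero_noise <- function(hr_mean = 70) {
  noise_model(ecg_sd = 0, scg_sd = 0, ppg_sd = 0, abp_sd = 0,
              burst_rate_hz = 0, hr_mean = hr_mean, hr_sd = 0)
}

#' Default task schedule
#'
#' The measurement segments of the protocol in order: sitting and standing
#' baselines, a rest period, the recovery periods following the mental
#' arithmetic and cold pressor perturbations, and the post-exercise recovery
#' split into early and late segments. Transit-time measurements exist only
#' in these segments (the device cannot record during the perturbations
#' themselves), so only they are scheduled.
#'
#' @param durations_s Named numeric vector of segment lengths (s). The
#'   default mirrors the protocol (2-minute baselines, 1-minute segments);
#'   [compact_schedule()] shortens every segment for simulation studies.
#' @return data.frame of task annotations laid end to end from t = 0.
#' @export
default_schedule <- function(durations_s = c(sit_baseline = 120,
                                             stand_baseline = 120,
                                             rest = 60,
                                             mental_arithmetic = 60,
                                             cold_pressor = 60,
                                             recovery_early = 60,
                                             recovery_late = 60)) {
  ends <- cumsum(durations_s)
  data.frame(label = names(durations_s),
             start_s = unname(ends - durations_s),
             end_s = unname(ends), stringsAsFactors = FALSE)
}

#' @rdname default_schedule
#' @param task_s Common segment length in seconds (>= 15 s keeps at least
#'   one full ensemble window per task at any plausible heart rate).
#' @export
compact_schedule <- function(task_s = 30) {
  d <- rep(task_s, 7)
  names(d) <- c("sit_baseline", "stand_baseline", "rest",
                "mental_arithmetic", "cold_pressor", "recovery_early",
                "recovery_late")
  default_schedule(d)
}

default_demographics <- function(participant_id = "sim01", age = 30,
                                 sex = "male", race = "other",
                                 height_cm = 172, weight_kg = 72) {
  demographics(participant_id, age = age, sex = sex, race = race,
               height_cm = height_cm, weight_kg = weight_kg)
}

#' Simulate one multichannel session
#'
#' Generates the seven synchronized 1 kHz channels. R times are laid down
#' with jittered R-R intervals (snapped to the sample grid); within each
#' scheduled task the beat's true transit time and pressure triple come from
#' the law; the SCG aortic-valve-opening marker falls at R + PEP, the PPG
#' diastolic foot and the ABP upstroke at R + PEP + PTT. Reference channels
#' (reference ECG, ABP) are delayed by an integer lag to exercise the
#' alignment stage. The returned ground-truth record satisfies
#' `ao_time = r_time + pep`, `foot_time = ao_time + ptt_true` and
#' `pat_true = foot_time - r_time` exactly by construction.
#'
#' @param law A [bp_law()].
#' @param noise A [noise_model()].
#' @param schedule Task annotation data.frame (see [default_schedule()]);
#'   tasks must be non-overlapping and each task label must appear in the
#'   law's task table. Every task must contain at least 12 beats.
#' @param seed Integer seed; identical seeds give identical sessions.
#' @param lag_samples Integer delay of the reference channels (samples).
#' @param templates Output of [make_beat_templates()].
#' @param demographics Participant demographics attached to the session.
#' @return List with elements `session` (a `ptt_session`) and `truth` (a
#'   `ptt_truth` record: per-beat fiducial table, per-task pressures, the
#'   law, noise model, lag and seed).
#' @export
simulate_session <- function(law, noise = noise_model(),
                             schedule = default_schedule(), seed = 1,
                             lag_samples = 250,
                             templates = make_beat_templates(),
                             demographics = default_demographics()) {
  stopifnot(inherits(law, "ptt_law"), inherits(noise, "ptt_noise"))
  fs <- 1000
  if (!all(schedule$label %in% law$tasks$task)) {
    stop("schedule contains task(s) missing from the law: ",
         paste(setdiff(schedule$label, law$tasks$task), collapse = ", "))
  }
  dur <- max(schedule$end_s)
  n <- round(dur * fs)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  # --- R-time grid (snapped to samples so noiseless beats are exact copies)
  rr_mean <- 60 / noise$hr_mean
  rr_sd <- 60 * noise$hr_sd / noise$hr_mean^2
  r <- 0.35
  r_times <- numeric(0)
  while (r < dur - 0.45) {
    r_times <- c(r_times, round(r * fs) / fs)
    rr <- rr_mean + if (rr_sd > 0) stats::rnorm(1, 0, rr_sd) else 0
    rr <- min(max(rr, rr_mean - 3 * rr_sd, 0.45), rr_mean + 3 * rr_sd)
    r <- r + rr
  }
  nb <- length(r_times) - 1L   # last R has no complete beat after it

  # task membership per beat
  idx_task <- findInterval(r_times[seq_len(nb)], schedule$start_s)
  idx_task[idx_task < 1L] <- 1L
  beat_task <- schedule$label[idx_task]
  per_task_beats <- table(factor(beat_task, levels = schedule$label))
  if (any(per_task_beats < 12)) {
    stop("schedule implies fewer than 12 beats in task(s): ",
         paste(names(per_task_beats)[per_task_beats < 12], collapse = ", "))
  }

  lt <- law$tasks[match(beat_task, law$tasks$task), ]
  truth_beats <- data.frame(
    beat = seq_len(nb), task = beat_task,
    r_time = r_times[seq_len(nb)],
    ao_time = r_times[seq_len(nb)] + law$pep_s,
    foot_time = r_times[seq_len(nb)] + law$pep_s + lt$ptt_s,
    ptt_true = lt$ptt_s,
    pat_true = law$pep_s + lt$ptt_s,
    dbp_true = lt$DBP, map_true = lt$MAP, sbp_true = lt$SBP,
    row.names = NULL)

  t_all <- (seq_len(n) - 1) / fs

  # --- additive templates: wearable ECG and SCG
  add_events <- function(fun, times, span) {
    out <- numeric(n)
    for (tt in times) {
      i0 <- max(1L, floor((tt + span[1]) * fs) + 1L)
      i1 <- min(n, ceiling((tt + span[2]) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      out[idx] <- out[idx] + fun(t_all[idx] - tt)
    }
    out
  }
  ecg_w <- add_events(templates$ecg, r_times, c(-0.06, 0.45))
  scg_w <- add_events(function(t) templates$scg(t, ao_s = law$pep_s),
                      r_times[seq_len(nb)], c(0, 0.35))

  # --- per-beat tiled waveforms: PPG (unit amplitude) and ABP
  ppg_base <- numeric(n)
  abp_base <- numeric(n)
  ppg_base[] <- templates$ppg(0, beat_len = 1, foot_s = 0.2) # pre-roll level
  abp_base[] <- truth_beats$dbp_true[1]
  for (b in seq_len(nb)) {
    i0 <- round(truth_beats$r_time[b] * fs) + 1L
    i1 <- round(r_times[b + 1L] * fs)
    blen <- (i1 - i0 + 1L) / fs
    tb <- t_all[i0:i1] - truth_beats$r_time[b]
    ppg_base[i0:i1] <- templates$ppg(tb, beat_len = blen,
                                     foot_s = truth_beats$pat_true[b])
    abp_base[i0:i1] <- templates$abp(tb, beat_len = blen,
                                     dbp = truth_beats$dbp_true[b],
                                     sbp = truth_beats$sbp_true[b],
                                     map = truth_beats$map_true[b],
                                     foot_s = truth_beats$pat_true[b])
  }
  # flat fill before the first and after the last beat
  first_i <- round(truth_beats$r_time[1] * fs)
  if (first_i >= 1L) {
    ppg_base[seq_len(first_i)] <- ppg_base[first_i + 1L]
    abp_base[seq_len(first_i)] <- abp_base[first_i + 1L]
  }
  last_i <- round(r_times[nb + 1L] * fs)
  if (last_i < n) {
    ppg_base[(last_i + 1L):n] <- ppg_base[last_i]
    abp_base[(last_i + 1L):n] <- abp_base[last_i]
  }

  # --- reference channels: identical morphology, delayed by lag_samples
  delay <- function(x, k) {
    if (k == 0L) return(x)
    if (k > 0L) c(rep(x[1], k), x[seq_len(n - k)])
    else c(x[(-k + 1L):n], rep(x[n], -k))
  }
  lag_samples <- as.integer(lag_samples)
  ecg_ref <- delay(ecg_w, lag_samples)
  abp_ref <- delay(abp_base, lag_samples)

  # --- noise
  add_noise <- function(x, sd) {
    if (sd <= 0) return(x)
    y <- x + stats::rnorm(n, 0, sd)
    if (noise$burst_rate_hz > 0) {
      n_burst <- stats::rpois(1, noise$burst_rate_hz * dur)
      if (n_burst > 0) {
        starts <- stats::runif(n_burst, 0, dur)
        durs <- stats::runif(n_burst, noise$burst_dur_s[1],
                             noise$burst_dur_s[2])
        for (k in seq_len(n_burst)) {
          i0 <- max(1L, round(starts[k] * fs))
          i1 <- min(n, round((starts[k] + durs[k]) * fs))
          idx <- i0:i1
          # band-limited burst: smoothed white noise, re-scaled
          w <- stats::rnorm(length(idx))
          w <- smooth_moving_average(w, fs, window_ms = 25)
          w <- w / max(stats::sd(w), 1e-12)
          y[idx] <- y[idx] + noise$burst_amp_mult * sd * w
        }
      }
    }
    y
  }
  chans <- list(
    channel("ecg_wearable", add_noise(ecg_w, noise$ecg_sd)),
    channel("scg_z", add_noise(scg_w, noise$scg_sd)),
    channel("ppg_green",
            add_noise(noise$ppg_amp_scale[["ppg_green"]] * ppg_base,
                      noise$ppg_sd)),
    channel("ppg_red",
            add_noise(noise$ppg_amp_scale[["ppg_red"]] * ppg_base,
                      noise$ppg_sd)),
    channel("ppg_ir",
            add_noise(noise$ppg_amp_scale[["ppg_ir"]] * ppg_base,
                      noise$ppg_sd)),
    channel("ecg_ref", add_noise(ecg_ref, noise$ecg_sd)),
    channel("abp", add_noise(abp_ref, noise$abp_sd))
  )

  ses <- session(demographics, chans, schedule)
  truth <- structure(
    list(beats = truth_beats, tasks = law$tasks, law = law, noise = noise,
         lag_samples = lag_samples, seed = seed),
    class = "ptt_truth")
  list(session = ses, truth = truth)
}

#' Group specification for cohort simulation
#'
#' Distributions for the diastolic calibration coefficients and
#' demographics of one cohort group. The MAP and SBP laws are derived from
#' the diastolic one with fixed component ratios (slopes 1.5x and 2.2x,
#' intercept offsets +11 and +32 mm Hg), keeping DBP <= MAP <= SBP while the
#' group contrast lives entirely in the diastolic coefficients.
#'
#' @param name Group label.
#' @param k1_dbp,k2_dbp Length-2 `c(mean, sd)` of the diastolic K1
#'   (mm Hg s) and K2 (mm Hg).
#' @param bmi,age Length-2 `c(mean, sd)` demographic distributions.
#' @param p_female Probability of sex `"female"`.
#' @param p_black Probability of race `"black"`.
#' @param noise A [noise_model()] used for every participant of the group.
#' @return An object of class `ptt_group_spec`.
#' @export
group_spec <- function(name, k1_dbp = c(2.4, 0.3), k2_dbp = c(61, 5),
                       bmi = c(25, 3), age = c(30, 8), p_female = 0.4,
                       p_black = 0.3, noise = zero_noise()) {
  stopifnot(length(k1_dbp) == 2, length(k2_dbp) == 2)
  structure(as.list(environment()), class = "ptt_group_spec")
}

sample_law_for <- function(spec) {
  k1d <- max(0.3, stats::rnorm(1, spec$k1_dbp[1], spec$k1_dbp[2]))
  k2d <- stats::rnorm(1, spec$k2_dbp[1], spec$k2_dbp[2])
  ptt <- seq(0.08, 0.28, length.out = 7) *
    stats::runif(7, 0.98, 1.02)
  names(ptt) <- c("sit_baseline", "stand_baseline", "rest",
                  "mental_arithmetic", "cold_pressor", "recovery_early",
                  "recovery_late")
  bp_law(K1 = c(DBP = k1d, MAP = 1.5 * k1d, SBP = 2.2 * k1d),
         K2 = c(DBP = k2d, MAP = k2d + 11, SBP = k2d + 32),
         task_ptt = ptt)
}

sample_demographics_for <- function(spec, id) {
  bmi <- max(17, stats::rnorm(1, spec$bmi[1], spec$bmi[2]))
  height <- stats::rnorm(1, 170, 9)
  demographics(participant_id = id,
               age = max(18, round(stats::rnorm(1, spec$age[1], spec$age[2]))),
               sex = if (stats::runif(1) < spec$p_female) "female" else "male",
               race = if (stats::runif(1) < spec$p_black) "black" else "other",
               height_cm = height,
               weight_kg = bmi * (height / 100)^2)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant laws and demographics from each group
#' specification. With `waveforms = TRUE` a full multichannel session is
#' generated per participant; with `waveforms = FALSE` only the sampled laws
#' and demographics are returned, which is the appropriate (and much
#' cheaper) input for operating-characteristic studies of the group
#' comparison statistics, where waveform-level recovery error (below 1% of
#' K1 on noiseless data) is negligible against the between-participant SD.
#'
#' @param group_specs List of [group_spec()] objects.
#' @param n_per_group Participants per group (positive).
#' @param seed Integer seed.
#' @param waveforms Generate full sessions (see Description).
#' @param schedule Schedule for generated sessions.
#' @return List with `sessions` (list of `ptt_session`, or `NULL` entries if
#'   `waveforms = FALSE`), `demographics` (one row per participant, with
#'   group), `truth` (data.frame of true coefficients per participant) and
#'   `records` (per-participant `ptt_truth`, when waveforms were built).
#' @export
simulate_cohort <- function(group_specs, n_per_group, seed = 1,
                            waveforms = TRUE,
                            schedule = compact_schedule()) {
  if (!length(group_specs)) stop("no groups given")
  if (n_per_group <= 0) stop("n_per_group must be positive")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sessions <- list(); records <- list()
  demo_rows <- list(); truth_rows <- list()
  pid <- 0L
  for (spec in group_specs) {
    for (i in seq_len(n_per_group)) {
      pid <- pid + 1L
      id <- sprintf("p%03d", pid)
      law <- sample_law_for(spec)
      dem <- sample_demographics_for(spec, id)
      demo_rows[[pid]] <- data.frame(
        participant_id = id, group = spec$name, age = dem$age,
        sex = dem$sex, race = dem$race, bmi = dem$bmi,
        obesity_class = dem$obesity_class, stringsAsFactors = FALSE)
      truth_rows[[pid]] <- data.frame(
        participant_id = id, group = spec$name,
        K1_DBP = law$K1[["DBP"]], K2_DBP = law$K2[["DBP"]],
        K1_MAP = law$K1[["MAP"]], K2_MAP = law$K2[["MAP"]],
        K1_SBP = law$K1[["SBP"]], K2_SBP = law$K2[["SBP"]],
        stringsAsFactors = FALSE)
      if (waveforms) {
        sim <- simulate_session(law, spec$noise, schedule = schedule,
                                seed = (seed %% 150000L) * 10000L + pid,
                                demographics = dem)
        sessions[[id]] <- sim$session
        records[[id]] <- sim$truth
      } else {
        sessions[id] <- list(NULL)
      }
    }
  }
  list(sessions = sessions,
       demographics = do.call(rbind, demo_rows),
       truth = do.call(rbind, truth_rows),
       records = if (waveforms) records else NULL)
}
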