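# End-to-end orchestration: align -> filter -> segment -> ensemble ->
# select -> gate -> fiducials -> calibrate -> estimate.

#' Pipeline configuration
#'
#' @param bands Filter band table ([filter_bands()]).
#' @param width,hop Ensemble window width and hop in beats (10/5 gives the
#'   50%-overlap windows the processing chain is built around).
#' @param wavelength PPG used for the transit time: `"ir"` (default, the
#'   most melanin-robust wavelength), `"red"` or `"green"`.
#' @param snr_thresholds Named `c(scg=, ppg=, abp=)` absolute SNR cutoffs in
#'   dB, or `NULL` for participant-specific thresholds
#'   ([snr_thresholds()]: 25th percentile of the participant's window
#'   SNRs).
#' @param foot_range_s Realistic pulse-arrival window for the foot gate.
#' @param pep_range_s Pre-ejection-period constraint for AO detection.
#' @param ao_mode `"earliest"` applies the first-qualifying-peak rule per
#'   task; `"consistent"` additionally prefers, per task, the candidate
#'   peak closest to the participant's median AO latency (the automated
#'   analogue of consistently annotating the same morphological peak).
#' @param prominence_frac AO peak prominence floor (fraction of beat
#'   peak-to-peak).
#' @param min_tasks Minimum kept tasks required to calibrate (default 4).
#' @param grade_thresholds Device-grading MAD thresholds, mm Hg.
#' @param max_lag_s Alignment search half-window (s).
#' @param guard_s Transition guard: beats starting within this many seconds
#'   of a task boundary are excluded from the ensembles, keeping band-pass
#'   transients caused by between-task pressure steps out of the averaged
#'   beats (the FIR impulse response spans 1 s either side).
#' @param top_frac PPG selection upstroke-pool fraction.
#' @param snr_fun SNR scoring function (swappable strategy; default
#'   [compute_snr()]).
#' @return A `ptt_config` list.
#' @export
run_config <- function(bands = filter_bands(), width = 10, hop = 5,
                       wavelength = c("ir", "red", "green"),
                       snr_thresholds = NULL,
                       foot_range_s = c(0.10, 0.50),
                       pep_range_s = c(0.03, 0.15),
                       ao_mode = c("earliest", "consistent"),
                       prominence_frac = 0.1, min_tasks = 4,
                       grade_thresholds = c(A = 5, B = 6, C = 7),
                       max_lag_s = 0.4, top_frac = 0.1, guard_s = 1,
                       snr_fun = compute_snr) {
  wavelength <- match.arg(wavelength)
  ao_mode <- match.arg(ao_mode)
  structure(as.list(environment()), class = "ptt_config")
}

filter_session_channels <- function(session, bands) {
  fs <- session$channels[[1]]$fs
  chans <- session$channels
  for (i in seq_len(nrow(bands))) {
    nm <- bands$channel[i]
    if (!nm %in% names(chans)) next
    x <- chans[[nm]]$samples
    chans[[nm]]$samples <- if (bands$kind[i] == "moving_average") {
      smooth_moving_average(x, fs, bands$window_ms[i])
    } else {
      bandpass_fir(x, fs, bands$f_lo[i], bands$f_hi[i])
    }
  }
  out <- session
  out$channels <- chans
  out
}

#' Run the full pipeline on one participant session
#'
#' Executes, in order: ECG cross-correlation alignment, per-modality
#' filtering, R-peak detection, task-wise beat segmentation (ensemble
#' windows never cross task boundaries), 10-beat/50%-overlap ensemble
#' averaging, SNR scoring, PPG beat selection (top-decile upstrokes then
#' max SNR) with its window-paired SCG beat, reference-pressure beat
#' selection (max SNR), fidelity gating, fiducial detection, per-component
#' calibration and pressure estimation. Deterministic given session and
#' config.
#'
#' @param session A `ptt_session` (aligned or not).
#' @param config A [run_config()].
#' @return A `ptt_participant`: list with `participant_id`, `fiducials`
#'   (per-task table: selection SNRs, gate outcome and reasons, foot/AO/PTT
#'   times, reference pressures), `calibration` (per-component K1/K2 table),
#'   `estimates` (per kept task and component: estimated and reference
#'   pressure), `thresholds`, and `uncalibratable` flag (fewer than
#'   `min_tasks` tasks survived the gate).
#' @export
run_participant <- function(session, config = run_config()) {
  stopifnot(inherits(session, "ptt_session"))
  fs <- session$channels[[1]]$fs
  if (is.na(session$alignment_lag_samples)) {
    session <- align_to_reference(session, config$max_lag_s)
  }
  flt <- filter_session_channels(session, config$bands)
  ppg_ch <- paste0("ppg_", config$wavelength)
  r_times <- detect_r_peaks(flt$channels[["ecg_wearable"]]$samples, fs)

  tasks <- flt$annotations
  per_task <- vector("list", nrow(tasks))
  for (ti in seq_len(nrow(tasks))) {
    task <- tasks$label[ti]
    rt <- r_times[r_times >= tasks$start_s[ti] + config$guard_s &
                    r_times < tasks$end_s[ti] - config$guard_s]
    row <- list(task = task, window = NA_integer_, upstroke = NA_real_,
                snr_ppg = NA_real_, snr_scg = NA_real_, snr_abp = NA_real_,
                foot_s = NA_real_, ao_s = NA_real_, ptt_s = NA_real_,
                pat_s = NA_real_, DBP = NA_real_, MAP = NA_real_,
                SBP = NA_real_, ao_candidates = list(numeric(0)),
                fail = NA_character_)
    if (length(rt) < config$width + 1) {
      row$fail <- "too_few_beats"
      per_task[[ti]] <- row
      next
    }
    ens <- lapply(c(ppg = ppg_ch, scg = "scg_z", abp = "abp"), function(nm) {
      bs <- segment_heartbeats(flt$channels[[nm]]$samples, rt, fs,
                               channel = nm)
      score_ensembles(ensemble_windows(bs, config$width, config$hop),
                      snr_fun = config$snr_fun)
    })
    names(ens) <- c("ppg", "scg", "abp")
    ens$scg <- lapply(ens$scg, function(e) { e$channel <- "scg_z"; e })
    i_ppg <- select_ppg_ensemble(ens$ppg, config$top_frac)
    i_abp <- select_reference_bp(ens$abp)
    e_ppg <- ens$ppg[[i_ppg]]
    e_scg <- ens$scg[[min(i_ppg, length(ens$scg))]]  # window-paired SCG
    e_abp <- ens$abp[[i_abp]]
    row$window <- i_ppg
    row$upstroke <- max_upstroke(e_ppg)
    row$snr_ppg <- e_ppg$snr_db
    row$snr_scg <- e_scg$snr_db
    row$snr_abp <- e_abp$snr_db
    row$all_snr <- list(ppg = vapply(ens$ppg, `[[`, numeric(1), "snr_db"),
                        scg = vapply(ens$scg, `[[`, numeric(1), "snr_db"),
                        abp = vapply(ens$abp, `[[`, numeric(1), "snr_db"))
    foot <- tryCatch(ppg_foot_intersecting_tangent(e_ppg$avg, fs),
                     error = function(e) NA_real_)
    row$foot_s <- row$pat_s <- foot   # beat start is the R peak
    if (is.finite(foot)) {
      cand <- tryCatch(
        detect_ao(e_scg$avg, fs, foot, config$pep_range_s,
                  config$prominence_frac, all_candidates = TRUE),
        error = function(e) numeric(0))
      row$ao_candidates <- list(cand)
      if (length(cand)) {
        row$ao_s <- cand[1]
        row$ptt_s <- foot - cand[1]
      }
    }
    bp <- abp_beat_bp(e_abp)
    row$DBP <- bp[["DBP"]]; row$MAP <- bp[["MAP"]]; row$SBP <- bp[["SBP"]]
    per_task[[ti]] <- row
  }

  # consistent-peak mode: per task, prefer the AO candidate closest to the
  # participant's median AO latency
  if (config$ao_mode == "consistent") {
    med <- stats::median(unlist(lapply(per_task, function(r) r$ao_s)),
                         na.rm = TRUE)
    if (is.finite(med)) {
      for (ti in seq_along(per_task)) {
        cand <- per_task[[ti]]$ao_candidates[[1]]
        if (length(cand) > 1) {
          ao <- cand[which.min(abs(cand - med))]
          per_task[[ti]]$ao_s <- ao
          per_task[[ti]]$ptt_s <- per_task[[ti]]$foot_s - ao
        }
      }
    }
  }

  # participant-specific thresholds from all window SNRs, unless absolute
  # cutoffs were configured
  thr <- config$snr_thresholds
  if (is.null(thr)) {
    pools <- list(scg = numeric(0), ppg = numeric(0), abp = numeric(0))
    for (r in per_task) {
      if (!is.null(r$all_snr)) {
        for (ch in names(pools)) pools[[ch]] <- c(pools[[ch]],
                                                  r$all_snr[[ch]])
      }
    }
    if (!length(pools$ppg)) stop("no usable task windows in session")
    thr <- snr_thresholds(pools)
  }
  thr <- thr[c("scg", "ppg", "abp")]

  fid <- do.call(rbind, lapply(per_task, function(r) {
    g <- if (!is.na(r$fail)) {
      list(kept = FALSE, reasons = r$fail)
    } else {
      gate_task(c(scg = r$snr_scg, ppg = r$snr_ppg, abp = r$snr_abp), thr,
                r$pat_s, config$foot_range_s,
                ao_found = is.finite(r$ao_s))
    }
    data.frame(task = r$task, window = r$window, upstroke = r$upstroke,
               snr_ppg = r$snr_ppg, snr_scg = r$snr_scg,
               snr_abp = r$snr_abp, foot_s = r$foot_s, ao_s = r$ao_s,
               ptt_s = r$ptt_s, pat_s = r$pat_s,
               DBP = r$DBP, MAP = r$MAP, SBP = r$SBP,
               kept = g$kept && is.finite(r$ptt_s),
               reasons = paste(g$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))

  kept <- fid[fid$kept, ]
  uncal <- nrow(kept) < config$min_tasks
  calibration <- NULL
  estimates <- NULL
  if (!uncal) {
    models <- lapply(c("DBP", "MAP", "SBP"), function(cc)
      fit_calibration(kept, cc))
    calibration <- do.call(rbind, lapply(models, function(m)
      data.frame(participant_id = session$demographics$participant_id,
                 component = m$component, K1 = m$K1, K2 = m$K2,
                 n_points = m$n_points, rmse = m$rmse,
                 stringsAsFactors = FALSE)))
    estimates <- do.call(rbind, lapply(models, function(m)
      data.frame(participant_id = session$demographics$participant_id,
                 task = kept$task, component = m$component,
                 ptt_s = kept$ptt_s,
                 estimated = estimate_bp(m, kept$ptt_s),
                 reference = kept[[m$component]],
                 stringsAsFactors = FALSE)))
  }
  structure(
    list(participant_id = session$demographics$participant_id,
         demographics = session$demographics,
         fiducials = fid, calibration = calibration, estimates = estimates,
         thresholds = thr, uncalibratable = uncal,
         wavelength = config$wavelength),
    class = "ptt_participant")
}

#' @export
print.ptt_participant <- function(x, ...) {
  cat("<ptt_participant>", x$participant_id,
      sprintf("| %d/%d tasks kept", sum(x$fiducials$kept),
              nrow(x$fiducials)),
      if (x$uncalibratable) "| UNCALIBRATABLE" else "", "\n")
  if (!is.null(x$calibration)) print(x$calibration, row.names = FALSE)
  invisible(x)
}

#' Run the study pipeline over a cohort
#'
#' Processes every session, pools the estimated/reference pressure pairs
#' into a per-component agreement report (pooled MAD and RMSE across all
#' pairs, plus the mean of per-participant RMSE and correlation, the
#' convention used when individual calibrations are reported), assembles
#' the calibration coefficient table, and runs the four demographic
#' comparisons on the diastolic coefficients.
#'
#' @param sessions List of `ptt_session` objects, or a directory containing
#'   session subdirectories written by [write_session()].
#' @param config A [run_config()].
#' @param groupings Demographic comparisons to run (may fail individually
#'   on small cohorts; failures are recorded as `NULL`).
#' @return A `ptt_study`: `participants` (list of `ptt_participant`),
#'   `agreement` (per component), `per_participant` (per-participant,
#'   per-component agreement), `calibration`, `demographics`,
#'   `comparisons`, `qc` (per task gate outcomes).
#' @export
run_study <- function(sessions, config = run_config(),
                      groupings = c("obesity", "sex", "race", "age")) {
  if (is.character(sessions)) {
    dirs <- list.dirs(sessions, recursive = FALSE)
    dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
    if (!length(dirs)) stop("no readable sessions in ", sessions)
    sessions <- lapply(dirs, read_session)
  }
  if (!length(sessions)) stop("no sessions given")
  participants <- lapply(sessions, run_participant, config = config)
  names(participants) <- vapply(participants, `[[`, character(1),
                                "participant_id")
  est <- do.call(rbind, lapply(participants, `[[`, "estimates"))
  calibration <- do.call(rbind, lapply(participants, `[[`, "calibration"))
  rownames(calibration) <- NULL
  demo <- do.call(rbind, lapply(participants, function(p) {
    d <- p$demographics
    data.frame(participant_id = d$participant_id, age = d$age, sex = d$sex,
               race = d$race, bmi = d$bmi, obesity_class = d$obesity_class,
               stringsAsFactors = FALSE)
  }))
  rownames(demo) <- NULL

  agreement <- NULL
  per_part <- NULL
  if (!is.null(est)) {
    agreement <- do.call(rbind, lapply(split(est, est$component),
      function(e) {
        a <- agreement_metrics(e$estimated, e$reference,
                               config$grade_thresholds)
        pp <- split(e, e$participant_id)
        a$mean_rmse <- mean(vapply(pp, function(q)
          sqrt(mean((q$estimated - q$reference)^2)), numeric(1)))
        a$mean_pcc <- mean(vapply(pp, function(q) {
          if (stats::sd(q$reference) == 0) NA_real_
          else stats::cor(q$estimated, q$reference)
        }, numeric(1)), na.rm = TRUE)
        cbind(component = e$component[1], a)
      }))
    rownames(agreement) <- NULL
    per_part <- do.call(rbind, lapply(
      split(est, list(est$participant_id, est$component), drop = TRUE),
      function(e) cbind(participant_id = e$participant_id[1],
                        component = e$component[1],
                        agreement_metrics(e$estimated, e$reference,
                                          config$grade_thresholds))))
    rownames(per_part) <- NULL
  }

  comparisons <- list()
  if (!is.null(calibration) && nrow(demo) >= 6) {
    for (g in groupings) {
      for (k in c("K1", "K2")) {
        key <- paste(g, k, sep = "_")
        comparisons[[key]] <- tryCatch(
          compare_groups(calibration, demo, g, k),
          error = function(e) NULL)
      }
    }
  }
  qc <- do.call(rbind, lapply(participants, function(p)
    cbind(participant_id = p$participant_id,
          p$fiducials[, c("task", "kept", "reasons")])))
  rownames(qc) <- NULL
  structure(
    list(participants = participants, agreement = agreement,
         per_participant = per_part, calibration = calibration,
         demographics = demo, comparisons = comparisons, qc = qc),
    class = "ptt_study")
}

#' @export
print.ptt_study <- function(x, ...) {
  cat("<ptt_study>", length(x$participants), "participants\n")
  if (!is.null(x$agreement)) {
    cols <- c("component", "n", "mad", "rmse", "pcc", "bias", "grade")
    print(x$agreement[, cols], row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Compare PPG wavelengths on per-participant estimation quality
#'
#' Re-runs the pipeline per wavelength, collects each participant's
#' diastolic correlation coefficient, and applies the paired Wilcoxon
#' signed-rank test between wavelengths.
#'
#' @param sessions List of `ptt_session`s.
#' @param config Base configuration (its `wavelength` is overridden).
#' @param component Pressure component compared (default DBP).
#' @return List with `pcc` (participant x wavelength data.frame) and
#'   `tests` (pairwise signed-rank results).
#' @export
compare_wavelengths <- function(sessions, config = run_config(),
                                component = "DBP") {
  wls <- c("green", "red", "ir")
  pcc <- NULL
  for (w in wls) {
    cfg <- config
    cfg$wavelength <- w
    st <- run_study(sessions, cfg, groupings = character())
    pp <- st$per_participant
    pp <- pp[pp$component == component, c("participant_id", "pcc")]
    names(pp)[2] <- w
    pcc <- if (is.null(pcc)) pp else merge(pcc, pp, by = "participant_id",
                                           all = TRUE)
  }
  tests <- list()
  for (pair in list(c("ir", "green"), c("red", "green"), c("ir", "red"))) {
    d <- pcc[[pair[1]]] - pcc[[pair[2]]]
    tests[[paste(pair, collapse = "_vs_")]] <-
      wilcoxon_signed_rank(d[is.finite(d)])
  }
  list(pcc = pcc, tests = tests)
}
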