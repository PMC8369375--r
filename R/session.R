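# Session data model: channels, task annotations, demographics.

#' Channel roles of a standard session
#'
#' The seven synchronized 1 kHz channels a session must carry: wearable ECG,
#' dorsoventral (z-axis) seismocardiogram, three wrist photoplethysmograms
#' (green/red/infrared), and the reference ECG plus continuous arterial
#' blood pressure from the finger-cuff system.
#'
#' @return Character vector of the seven required channel names.
#' @export
session_channel_roles <- function() {
  c("ecg_wearable", "scg_z", "ppg_green", "ppg_red", "ppg_ir",
    "ecg_ref", "abp")
}

#' @rdname session_channel_roles
#' @export
ppg_wavelengths_nm <- function() {
  c(ppg_green = 526, ppg_red = 660, ppg_ir = 950)
}

reference_channel_roles <- function() c("ecg_ref", "abp")

task_labels <- function() {
  c("sit_baseline", "stand_baseline", "rest", "mental_arithmetic",
    "cold_pressor", "exercise", "recovery_early", "recovery_late")
}

#' Construct a single-channel record
#'
#' @param name Channel name. The seven standard roles are listed by
#'   [session_channel_roles()]; other names are allowed and round-trip
#'   through session files untouched.
#' @param samples Numeric vector of samples in physical units (mm Hg for
#'   `abp`, g for `scg_z`, arbitrary units otherwise).
#' @param fs Sampling rate in Hz (1000 for all standard channels).
#' @param wavelength_nm LED wavelength in nm for PPG channels; filled in
#'   automatically for the three standard PPG roles.
#' @return An object of class `ptt_channel`.
#' @export
channel <- function(name, samples, fs = 1000, wavelength_nm = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.numeric(samples))
  wl <- ppg_wavelengths_nm()
  if (is.null(wavelength_nm) && name %in% names(wl)) {
    wavelength_nm <- unname(wl[[name]])
  }
  structure(
    list(name = name, samples = as.numeric(samples), fs = fs,
         wavelength_nm = wavelength_nm),
    class = "ptt_channel"
  )
}

#' Task annotation
#'
#' Half-open interval `[start_s, end_s)` in seconds from record start,
#' labelled with one of the protocol tasks (baselines, perturbations, rest
#' and recovery segments).
#'
#' @param label Task label; see `Details`.
#' @param start_s,end_s Interval bounds in seconds, `start_s < end_s`.
#' @return A one-row data.frame with columns `label`, `start_s`, `end_s`.
#' @details Recognized labels: `sit_baseline`, `stand_baseline`, `rest`,
#'   `mental_arithmetic`, `cold_pressor`, `exercise`, `recovery_early`,
#'   `recovery_late`.
#' @export
task_annotation <- function(label, start_s, end_s) {
  if (!label %in% task_labels()) {
    stop("unknown task label: ", label)
  }
  if (!(start_s < end_s)) stop("task annotation requires start_s < end_s")
  data.frame(label = label, start_s = start_s, end_s = end_s,
             stringsAsFactors = FALSE)
}

#' Participant demographics
#'
#' @param participant_id Identifier (character or integer).
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param race Free-form label; `"black"` is the level used by the race
#'   stratification in [compare_groups()].
#' @param height_cm,weight_kg Height (cm) and weight (kg).
#' @param bmi Body-mass index in kg/m^2; computed from height and weight
#'   when omitted. Must agree with `weight/height^2` within 0.1.
#' @param hypertensive_status One of `"normotensive"`, `"hypertensive"`,
#'   `"hypotensive"`.
#' @param medications Character vector of current medications.
#' @return An object of class `ptt_demographics`. The obesity class is
#'   derived from BMI (nonobese < 30; I 30-34.9; II 35-39.9; III >= 40).
#' @export
demographics <- function(participant_id, age, sex, race,
                         height_cm, weight_kg, bmi = NULL,
                         hypertensive_status = "normotensive",
                         medications = character()) {
  sex <- match.arg(sex, c("male", "female"))
  hypertensive_status <- match.arg(
    hypertensive_status, c("normotensive", "hypertensive", "hypotensive"))
  bmi_calc <- weight_kg / (height_cm / 100)^2
  if (is.null(bmi)) bmi <- bmi_calc
  structure(
    list(participant_id = as.character(participant_id), age = age, sex = sex,
         race = race, height_cm = height_cm, weight_kg = weight_kg,
         bmi = bmi, obesity_class = obesity_class(bmi),
         hypertensive_status = hypertensive_status,
         medications = as.character(medications)),
    class = "ptt_demographics"
  )
}

#' Obesity class from BMI
#'
#' Classes follow the NHLBI convention: `nonobese` below 30 kg/m^2,
#' class `I` 30-34.9, class `II` 35-39.9, class `III` at or above 40.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2).
#' @return Character vector of classes.
#' @export
obesity_class <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 30, 35, 40, Inf), right = FALSE,
      labels = c("nonobese", "I", "II", "III")) |> as.character()
}

#' Assemble a multichannel session
#'
#' @param demographics A [demographics()] object.
#' @param channels List of [channel()] objects (names taken from each
#'   channel). A complete session carries all of
#'   [session_channel_roles()]; extra channels are preserved.
#' @param annotations data.frame of task annotations (rows from
#'   [task_annotation()], usually a schedule such as [default_schedule()]).
#' @param alignment_lag_samples Integer lag applied by
#'   [align_to_reference()], or `NA` if the session has not been aligned.
#' @return An object of class `ptt_session`.
#' @export
session <- function(demographics, channels, annotations,
                    alignment_lag_samples = NA_integer_) {
  stopifnot(inherits(demographics, "ptt_demographics"))
  nm <- vapply(channels, function(ch) ch$name, character(1))
  names(channels) <- nm
  structure(
    list(demographics = demographics, channels = channels,
         annotations = annotations,
         alignment_lag_samples = alignment_lag_samples),
    class = "ptt_session"
  )
}

#' @export
print.ptt_session <- function(x, ...) {
  n <- lengths(lapply(x$channels, `[[`, "samples"))
  cat("<ptt_session> participant", x$demographics$participant_id, "\n")
  cat("  channels:", paste0(names(x$channels), " [", n, "]", collapse = ", "),
      "\n")
  cat("  tasks:", nrow(x$annotations),
      "| aligned:", !is.na(x$alignment_lag_samples), "\n")
  invisible(x)
}

#' Validate a session against the schema invariants
#'
#' Report-only check of the session contract: 1 kHz sampling on every
#' channel, presence of the seven required roles, wavelength metadata on PPG
#' channels (and none elsewhere), finite samples, non-overlapping in-range
#' annotations, and BMI consistency.
#'
#' @param session A `ptt_session`.
#' @return A data.frame with columns `check` and `message`; zero rows means
#'   the session is valid.
#' @export
validate_session <- function(session) {
  bad <- list()
  note <- function(check, message) {
    bad[[length(bad) + 1L]] <<- data.frame(check = check, message = message,
                                           stringsAsFactors = FALSE)
  }
  missing <- setdiff(session_channel_roles(), names(session$channels))
  if (length(missing)) {
    note("channels", paste("missing required channel(s):",
                           paste(missing, collapse = ", ")))
  }
  for (ch in session$channels) {
    if (!identical(as.numeric(ch$fs), 1000)) {
      note("fs", sprintf("channel %s: fs != 1000 (got %s)", ch$name, ch$fs))
    }
    if (length(ch$samples) && !all(is.finite(ch$samples))) {
      note("finite", sprintf("channel %s: non-finite samples", ch$name))
    }
    is_ppg <- grepl("^ppg_", ch$name)
    if (is_ppg && is.null(ch$wavelength_nm)) {
      note("wavelength", sprintf("PPG channel %s lacks wavelength_nm", ch$name))
    }
    if (!is_ppg && !is.null(ch$wavelength_nm)) {
      note("wavelength", sprintf("non-PPG channel %s carries wavelength_nm",
                                 ch$name))
    }
  }
  ann <- session$annotations
  if (!is.null(ann) && nrow(ann)) {
    if (any(ann$start_s >= ann$end_s)) {
      note("annotations", "annotation with start_s >= end_s")
    }
    o <- order(ann$start_s)
    if (nrow(ann) > 1L &&
        any(ann$end_s[o][-nrow(ann)] > ann$start_s[o][-1L] + 1e-9)) {
      note("annotations", "overlapping annotations")
    }
    dur <- min(lengths(lapply(session$channels, `[[`, "samples"))) / 1000
    if (length(session$channels) && max(ann$end_s) > dur + 1e-9) {
      note("annotations", "annotation extends past record duration")
    }
  }
  d <- session$demographics
  if (abs(d$bmi - d$weight_kg / (d$height_cm / 100)^2) > 0.1) {
    note("demographics", "bmi inconsistent with weight/height^2")
  }
  if (!is.na(session$alignment_lag_samples)) {
    n <- lengths(lapply(session$channels, `[[`, "samples"))
    if (length(unique(n)) > 1L) {
      note("alignment", "aligned session has unequal channel lengths")
    }
  }
  if (!length(bad)) {
    data.frame(check = character(), message = character())
  } else {
    do.call(rbind, bad)
  }
}

# Stop with a readable message when a session is invalid.
assert_valid_session <- function(session) {
  v <- validate_session(session)
  if (nrow(v)) {
    stop("invalid session: ", paste(v$message, collapse = "; "))
  }
  invisible(session)
}
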