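# Session round-trip: one directory per session, channels as CSV, metadata
# as JSON. A plain-text container keeps sessions inspectable with standard
# tools and round-trips losslessly (data.table writes shortest round-trip
# decimal representations).

SESSION_FORMAT_VERSION <- "1.0"

#' Write a session to disk
#'
#' Stores a session as a directory: `meta.json` (format version,
#' demographics, annotations, per-channel metadata, alignment lag) plus one
#' `channel-<name>.csv` per channel holding the sample vector. Writing the
#' same session twice produces byte-identical files.
#'
#' @param session A valid `ptt_session`.
#' @param path Directory to create (or overwrite) for this session.
#' @return `path`, invisibly.
#' @seealso [read_session()], [export_channels_csv()]
#' @export
write_session <- function(session, path) {
  assert_valid_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)
  chan_meta <- lapply(unname(session$channels), function(ch) {
    list(name = ch$name, fs = ch$fs,
         wavelength_nm = ch$wavelength_nm,  # NULL drops out for non-PPG
         n = length(ch$samples))
  })
  d <- session$demographics
  meta <- list(
    format_version = SESSION_FORMAT_VERSION,
    demographics = d[setdiff(names(d), NULL)],
    annotations = session$annotations,
    channels = chan_meta,
    alignment_lag_samples = session$alignment_lag_samples
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  for (ch in session$channels) {
    data.table::fwrite(list(value = ch$samples),
                       file.path(path, paste0("channel-", ch$name, ".csv")))
  }
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path Session directory.
#' @return A `ptt_session`. Metadata is restored exactly; samples within
#'   float round-trip precision. Channels not among the standard roles are
#'   preserved.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a session directory (no meta.json): ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(meta$format_version, SESSION_FORMAT_VERSION)) {
    stop("session format version mismatch: found ",
         meta$format_version %||% "<none>", ", expected ",
         SESSION_FORMAT_VERSION)
  }
  dm <- meta$demographics
  d <- demographics(
    participant_id = dm$participant_id, age = dm$age, sex = dm$sex,
    race = dm$race, height_cm = dm$height_cm, weight_kg = dm$weight_kg,
    bmi = dm$bmi, hypertensive_status = dm$hypertensive_status,
    medications = unlist(dm$medications) %||% character())
  cm <- meta$channels
  chans <- lapply(seq_len(nrow(cm)), function(i) {
    f <- file.path(path, paste0("channel-", cm$name[i], ".csv"))
    if (!file.exists(f)) stop("missing channel file: ", f)
    x <- data.table::fread(f, colClasses = "numeric")$value
    if (length(x) != cm$n[i]) {
      stop(sprintf("corrupt channel length for %s: expected %d, found %d",
                   cm$name[i], cm$n[i], length(x)))
    }
    wl <- if ("wavelength_nm" %in% names(cm)) cm$wavelength_nm[i] else NA
    channel(cm$name[i], x, fs = as.numeric(cm$fs[i]),
            wavelength_nm = if (is.null(wl) || is.na(wl)) NULL else wl)
  })
  ann <- as.data.frame(meta$annotations)
  lag <- meta$alignment_lag_samples
  session(d, chans, ann,
          alignment_lag_samples = if (is.null(lag) || is.na(lag))
            NA_integer_ else as.integer(lag))
}

#' Export session channels as a single tidy CSV
#'
#' Long-format export with columns `t_s`, `channel`, `value`, for use
#' outside R. Requires equal channel lengths (i.e. an aligned or simulated
#' session).
#'
#' @param session A `ptt_session`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
export_channels_csv <- function(session, file) {
  n <- lengths(lapply(session$channels, `[[`, "samples"))
  if (length(unique(n)) != 1L) {
    stop("channels have unequal lengths; align the session first")
  }
  fs <- session$channels[[1]]$fs
  dt <- data.table::data.table(t_s = (seq_len(n[[1]]) - 1) / fs)
  for (ch in session$channels) dt[[ch$name]] <- ch$samples
  data.table::fwrite(dt, file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
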