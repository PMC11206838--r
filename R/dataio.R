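#' @importFrom stats approx var sd rnorm runif setNames aggregate median
#' @importFrom utils read.table write.table head tail
NULL

MUSCLES <- c("LG", "MG", "SOL", "TA")
PLANTAR_FLEXORS <- c("LG", "MG", "SOL")
TRIAL_COLUMNS <- c(
  "time_s", "com_pos_m", "ankle_angle_deg",
  "emg_LG", "emg_MG", "emg_SOL", "emg_TA"
)

#' Construct a trial recording
#'
#' A trial recording holds one perturbation trial: the anterior-posterior
#' centre-of-mass position relative to the ankle (metres, anterior
#' positive), the ankle angle (degrees, dorsiflexion positive) and the four
#' raw or envelope EMG channels (lateral/medial gastrocnemius, soleus,
#' tibialis anterior), plus trial metadata. All series share the `time_s`
#' axis; `onset_time` marks perturbation onset on that axis and every
#' downstream analysis re-references time so onset = 0.
#'
#' @param subject_id Subject identifier string.
#' @param group Group label, `"CP"` or `"TD"`.
#' @param level Perturbation level, integer 1-4.
#' @param trial_index Trial number within the level.
#' @param stepped Logical; `TRUE` if the participant stepped (trial is
#'   excluded from averaging downstream).
#' @param onset_time Perturbation onset in seconds on the `time_s` axis.
#' @param time_s Sample times, strictly increasing, seconds.
#' @param com_pos Anterior-posterior CoM position relative to the ankle (m).
#' @param ankle_angle Ankle angle (deg, dorsiflexion positive).
#' @param emg Named list of the four EMG channels (`LG`, `MG`, `SOL`, `TA`).
#' @param emg_rate,kin_rate Sampling rates (Hz) of the EMG and kinematic
#'   channels as recorded; the file itself stores everything on `time_s`.
#' @param emg_kind `"envelope"` if the EMG channels are already linear
#'   envelopes (the synthetic default), `"raw"` if they are unprocessed
#'   interference signals that still need the filter chain.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, group, level, trial_index, stepped,
                            onset_time, time_s, com_pos, ankle_angle, emg,
                            emg_rate = 1000, kin_rate = 100,
                            emg_kind = c("envelope", "raw")) {
  emg_kind <- match.arg(emg_kind)
  group <- match.arg(group, c("CP", "TD"))
  if (!level %in% 1:4) stop("level must be in 1..4, got ", level)
  if (!setequal(names(emg), MUSCLES)) {
    stop("emg must have exactly the channels ", paste(MUSCLES, collapse = ", "))
  }
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  n <- length(time_s)
  lens <- c(length(com_pos), length(ankle_angle),
            vapply(emg, length, integer(1)))
  if (any(lens != n)) stop("all channels must match time_s in length")
  if (emg_rate <= 0 || kin_rate <= 0) stop("sampling rates must be positive")
  if (emg_rate < kin_rate) stop("EMG rate must be >= kinematic rate")
  rec <- structure(
    list(
      subject_id = as.character(subject_id), group = group,
      level = as.integer(level), trial_index = as.integer(trial_index),
      stepped = isTRUE(stepped), onset_time = onset_time,
      time_s = time_s, com_pos = com_pos, ankle_angle = ankle_angle,
      emg = emg[MUSCLES], emg_rate = emg_rate, kin_rate = kin_rate,
      emg_kind = emg_kind
    ),
    class = "trial_recording"
  )
  rec
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> subject %s (%s) level %d trial %d%s\n  %d samples, t = [%.3f, %.3f] s, onset %.3f s, EMG %s\n",
    x$subject_id, x$group, x$level, x$trial_index,
    if (x$stepped) " [stepped]" else "",
    length(x$time_s), min(x$time_s), max(x$time_s), x$onset_time, x$emg_kind
  ))
  invisible(x)
}

#' Read one trial file
#'
#' Trial files are tab-separated text with a one-line header and the fixed
#' columns `time_s, com_pos_m, ankle_angle_deg, emg_LG, emg_MG, emg_SOL,
#' emg_TA`. Metadata (subject, group, level, onset, rates) comes from the
#' manifest entry, not from the file.
#'
#' @param path Path to the trial file.
#' @param meta A manifest entry: a list with fields `subject_id`, `group`,
#'   `level`, `trial`, `stepped`, `onset_time_s`, `emg_rate_hz`,
#'   `kin_rate_hz` and optionally `emg_kind`.
#' @return A [trial_recording()].
#' @export
read_trial <- function(path, meta) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing)) {
    stop("trial file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("non-monotonic time_s in ", path)
  }
  trial_recording(
    subject_id = meta$subject_id, group = meta$group, level = meta$level,
    trial_index = meta$trial, stepped = isTRUE(meta$stepped),
    onset_time = meta$onset_time_s,
    time_s = df$time_s, com_pos = df$com_pos_m,
    ankle_angle = df$ankle_angle_deg,
    emg = list(LG = df$emg_LG, MG = df$emg_MG,
               SOL = df$emg_SOL, TA = df$emg_TA),
    emg_rate = meta$emg_rate_hz %||% 1000,
    kin_rate = meta$kin_rate_hz %||% 100,
    emg_kind = meta$emg_kind %||% "envelope"
  )
}

#' Write one trial file
#'
#' Inverse of [read_trial()]: values round-trip within 1e-9 (15 significant
#' digits are written). `NA` samples are permitted and round-trip as `NA`.
#'
#' @param rec A [trial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  stopifnot(inherits(rec, "trial_recording"))
  df <- data.frame(
    time_s = rec$time_s, com_pos_m = rec$com_pos,
    ankle_angle_deg = rec$ankle_angle,
    emg_LG = rec$emg$LG, emg_MG = rec$emg$MG,
    emg_SOL = rec$emg$SOL, emg_TA = rec$emg$TA
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  old <- options(digits = 15)
  on.exit(options(old))
  tryCatch(
    write.table(format(df, digits = 15, trim = TRUE, scientific = TRUE),
                path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write trial file ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

manifest_entry_fields <- c(
  "path", "subject_id", "group", "level", "trial",
  "onset_time_s", "stepped", "emg_rate_hz", "kin_rate_hz"
)

#' Load a dataset manifest
#'
#' The manifest is a JSON file with a `schema_version` string and an
#' `entries` array; each entry carries a trial file path (relative to the
#' manifest) plus the trial metadata. Subject/level/trial triples must be
#' unique and every referenced file must exist.
#'
#' @param path Path to the manifest JSON.
#' @return A list with `schema_version`, `entries` (each with an absolute
#'   `path`), and `root` (the manifest directory).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(m$entries)) stop("manifest has no 'entries' field")
  root <- dirname(normalizePath(path))
  keys <- vapply(m$entries, function(e)
    paste(e$subject_id, e$level, e$trial, sep = "/"), character(1))
  dup <- keys[duplicated(keys)]
  if (length(dup)) {
    stop("duplicate subject/level/trial in manifest: ",
         paste(unique(dup), collapse = ", "))
  }
  m$entries <- lapply(m$entries, function(e) {
    missing <- setdiff(manifest_entry_fields, names(e))
    if (length(missing)) {
      stop("manifest entry lacks field(s): ", paste(missing, collapse = ", "))
    }
    p <- e$path
    if (!grepl("^/", p)) p <- file.path(root, p)
    if (!file.exists(p)) stop("manifest references missing file: ", e$path)
    e$path <- p
    e
  })
  m$root <- root
  m
}

#' Write a dataset manifest
#'
#' @param entries List of manifest entries (see [load_manifest()]).
#' @param path Output path; entry paths are stored relative to it when
#'   possible.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  m <- list(schema_version = "1.0", entries = entries)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
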