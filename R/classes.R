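#' Standard 16-channel montage
#'
#' The electrode set used throughout the package: sixteen 10-20 positions
#' over frontal, central and parietal cortex, referenced to the right
#' earlobe (A2).
#'
#' @param names Character vector of electrode labels. Defaults to the
#'   16-channel montage `Fz, F3, FC2, FC1, FC5, C2, Cz, C1, C3, C5, T3,
#'   Cp2, Cp1, Cp5, Pz, P3`.
#' @param reference Reference electrode label, default `"A2"`.
#' @return A `channel_layout` object.
#' @export
channel_layout <- function(names = default_channels(), reference = "A2") {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("channel names must be unique")
  if (length(names) < 1) stop("at least one channel required")
  structure(list(names = names, reference = reference),
            class = "channel_layout")
}

#' @rdname channel_layout
#' @export
default_channels <- function() {
  c("Fz", "F3", "FC2", "FC1", "FC5", "C2", "Cz", "C1", "C3", "C5",
    "T3", "Cp2", "Cp1", "Cp5", "Pz", "P3")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("<channel_layout> ", length(x$names), " channels, ref ", x$reference,
      "\n  ", paste(x$names, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Multichannel EEG recording
#'
#' A channels-by-samples matrix of scalp potentials in microvolts with its
#' sampling rate and montage.
#'
#' @param data Numeric matrix, channels in rows, samples in columns, in
#'   microvolts. Row order must follow `layout$names`.
#' @param fs Sampling rate in Hz (default 500).
#' @param layout A [channel_layout()]; defaults to the standard montage if
#'   the matrix has 16 rows, otherwise labels `ch1..chN`.
#' @param t0 Recording start time in seconds (default 0).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs = 500, layout = NULL, t0 = 0) {
  data <- as.matrix(data)
  if (is.null(layout)) {
    layout <- if (nrow(data) == 16L) channel_layout()
              else channel_layout(paste0("ch", seq_len(nrow(data))))
  }
  if (nrow(data) != length(layout$names))
    stop("layout mismatch: data has ", nrow(data), " rows but layout names ",
         length(layout$names), " channels")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  if (!all(is.finite(data))) stop("non-finite data")
  rownames(data) <- layout$names
  structure(list(layout = layout, fs = fs, data = data, t0 = t0),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2),
      " s)\n", sep = "")
  invisible(x)
}

#' Number of samples / duration helpers
#' @param x An `eeg_recording` or `kinematics_trace`.
#' @return Sample count (`n_samples`) or duration in seconds (`duration_s`).
#' @export
n_samples <- function(x) {
  if (inherits(x, "eeg_recording")) ncol(x$data)
  else if (inherits(x, "kinematics_trace")) length(x$shoulder_deg)
  else stop("unsupported type")
}

#' @rdname n_samples
#' @export
duration_s <- function(x) n_samples(x) / x$fs

#' Cue schedule
#'
#' Ordered auditory cues, each initiating one motion: class `+1` for arm
#' lifting, `-1` for hand reaching. Sessions start with an initial rest
#' period before the first cue.
#'
#' @param events Data frame with columns `time_s` and `class`
#'   (`+1` lifting / `-1` reaching), time-ordered.
#' @param rest_lead_s Initial rest duration in seconds (default 10).
#' @return A `cue_schedule` object.
#' @export
cue_schedule <- function(events, rest_lead_s = 10) {
  events <- as.data.frame(events)
  if (nrow(events) > 0) {
    stopifnot(all(c("time_s", "class") %in% names(events)))
    if (is.unsorted(events$time_s, strictly = TRUE))
      stop("clock error: cue times must be strictly increasing")
    if (!all(events$class %in% c(-1, 1)))
      stop("cue class codes must be +1 (lifting) or -1 (reaching)")
  } else {
    events <- data.frame(time_s = numeric(0), class = numeric(0))
  }
  structure(list(events = events, rest_lead_s = rest_lead_s),
            class = "cue_schedule")
}

#' @export
print.cue_schedule <- function(x, ...) {
  cat("<cue_schedule> ", nrow(x$events), " cues (",
      sum(x$events$class == 1), " lifting / ",
      sum(x$events$class == -1), " reaching), initial rest ",
      x$rest_lead_s, " s\n", sep = "")
  invisible(x)
}

#' Upper-limb kinematics trace
#'
#' Synchronised shoulder and elbow flexion/extension angles plus the hand
#' endpoint in a shoulder-centred plane (x forward, y up, metres).
#'
#' @param fs Sampling rate in Hz.
#' @param shoulder_deg,elbow_deg Angle series in degrees, within 0-180.
#' @param endpoint_xy Two-column matrix of (x, y) endpoint positions in
#'   metres, same length as the angle series.
#' @return A `kinematics_trace` object.
#' @export
kinematics_trace <- function(fs, shoulder_deg, elbow_deg, endpoint_xy) {
  endpoint_xy <- as.matrix(endpoint_xy)
  n <- length(shoulder_deg)
  if (length(elbow_deg) != n || nrow(endpoint_xy) != n)
    stop("kinematic series must have equal length")
  if (ncol(endpoint_xy) != 2) stop("endpoint_xy must have two columns")
  rng <- range(shoulder_deg, elbow_deg)
  if (rng[1] < 0 || rng[2] > 180)
    stop("angles must lie within [0, 180] degrees")
  colnames(endpoint_xy) <- c("x", "y")
  structure(list(fs = fs, shoulder_deg = as.numeric(shoulder_deg),
                 elbow_deg = as.numeric(elbow_deg),
                 endpoint_xy = endpoint_xy),
            class = "kinematics_trace")
}

#' @export
print.kinematics_trace <- function(x, ...) {
  cat("<kinematics_trace> ", length(x$shoulder_deg), " samples @ ", x$fs,
      " Hz; shoulder ", round(min(x$shoulder_deg), 1), "-",
      round(max(x$shoulder_deg), 1), " deg\n", sep = "")
  invisible(x)
}

#' One recording session
#'
#' Bundles the EEG, cue schedule, kinematics (resampled to the EEG clock)
#' and per-sample motion labels for one subject.
#'
#' @param subject_id Subject identifier string.
#' @param eeg An [eeg_recording()].
#' @param schedule A [cue_schedule()].
#' @param kin A [kinematics_trace()] aligned to the EEG clock (same `fs`
#'   and sample count).
#' @param labels Integer-valued per-sample class series in `{-1, 0, +1}`
#'   (reaching / rest / lifting), same length as the EEG.
#' @return A `session_bundle` object.
#' @export
session_bundle <- function(subject_id, eeg, schedule, kin, labels) {
  stopifnot(inherits(eeg, "eeg_recording"), inherits(schedule, "cue_schedule"),
            inherits(kin, "kinematics_trace"))
  labels <- as.numeric(labels)
  if (length(labels) != ncol(eeg$data))
    stop("labels length must equal EEG sample count")
  if (!all(labels %in% c(-1, 0, 1)))
    stop("labels must be in {-1, 0, +1}")
  if (length(kin$shoulder_deg) != ncol(eeg$data) || kin$fs != eeg$fs)
    stop("kinematics must be aligned to the EEG clock")
  structure(list(subject_id = as.character(subject_id), eeg = eeg,
                 schedule = schedule, kin = kin, labels = labels),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle> subject ", x$subject_id, ": ", sep = "")
  print(x$eeg)
  print(x$schedule)
  invisible(x)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
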