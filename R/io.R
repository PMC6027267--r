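#' Resample a kinematics trace
#'
#' Linear interpolation onto a new clock. The sample count maps as
#' `round(n * fs_out / fs_in)`, preserving total duration to within one
#' sample period.
#'
#' @param kin A [kinematics_trace()].
#' @param fs_out Target rate in Hz.
#' @param n_out Optional explicit output sample count.
#' @return A [kinematics_trace()] at `fs_out`.
#' @export
resample_kinematics <- function(kin, fs_out, n_out = NULL) {
  n_in <- length(kin$shoulder_deg)
  if (is.null(n_out)) n_out <- as.integer(round(n_in * fs_out / kin$fs))
  t_in <- (seq_len(n_in) - 1) / kin$fs
  t_out <- (seq_len(n_out) - 1) / fs_out
  rs <- function(v) stats::approx(t_in, v, xout = t_out, rule = 2)$y
  kinematics_trace(fs_out, rs(kin$shoulder_deg), rs(kin$elbow_deg),
                   cbind(rs(kin$endpoint_xy[, 1]), rs(kin$endpoint_xy[, 2])))
}

#' Per-sample class labels from a cue schedule
#'
#' Each cue claims the window up to the next cue (or session end). Within
#' it, the movement span is taken from the limb-motion detector
#' ([limb_motion_flag()]): the labelled span runs from the first to the
#' last flagged sample, half-open, and receives the cue's class code.
#' Everything else -- including the initial rest lead -- is 0.
#'
#' @param schedule A [cue_schedule()].
#' @param kin A [kinematics_trace()] aligned to the target clock.
#' @param n_samples Length of the label track.
#' @param fs Sampling rate of the label track in Hz.
#' @param vel_thresh_deg_s,hold_ms Detector settings, see
#'   [limb_motion_flag()].
#' @return Numeric series in `{-1, 0, +1}` of length `n_samples`.
#' @export
label_track_from_schedule <- function(schedule, kin, n_samples, fs,
                                      vel_thresh_deg_s = 10, hold_ms = 200) {
  labels <- numeric(n_samples)
  ev <- schedule$events
  if (nrow(ev) == 0) return(labels)
  if (any(ev$time_s * fs >= n_samples)) stop("schedule overrun")
  flag <- limb_motion_flag(kin, vel_thresh_deg_s, hold_ms)
  flag <- flag[seq_len(min(length(flag), n_samples))]
  lead_n <- as.integer(round(schedule$rest_lead_s * fs))
  bounds <- c(floor(ev$time_s * fs) + 1L, n_samples + 1L)
  for (i in seq_len(nrow(ev))) {
    win <- bounds[i]:(bounds[i + 1L] - 1L)
    win <- win[win <= length(flag)]
    hit <- win[flag[win]]
    if (!length(hit)) next
    span <- hit[1]:hit[length(hit)]
    span <- span[span > lead_n]
    labels[span] <- ev$class[i]
  }
  labels
}

meta_filename <- "metadata.yaml"

#' Write a session bundle to disk
#'
#' A session is a directory of UTF-8 delimited-text files plus a YAML
#' metadata sidecar: `eeg.csv` (one column per channel, microvolts),
#' `schedule.csv`, `kinematics.csv` (degrees / metres), `labels.csv`, and
#' `metadata.yaml` (subject id, rates, units, montage). Identical bundles
#' produce byte-identical files.
#'
#' @param s A [session_bundle()].
#' @param path Target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  stopifnot(inherits(s, "session_bundle"))
  if (!all(is.finite(s$eeg$data)) || !all(is.finite(s$kin$shoulder_deg)))
    stop("non-finite data")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("unwritable path: ", path)
  fw <- function(d, f) data.table::fwrite(d, file.path(path, f), sep = ",")
  eeg_dt <- data.table::as.data.table(t(s$eeg$data))
  data.table::setnames(eeg_dt, s$eeg$layout$names)
  fw(eeg_dt, "eeg.csv")
  fw(s$schedule$events, "schedule.csv")
  fw(data.frame(shoulder_deg = s$kin$shoulder_deg,
                elbow_deg = s$kin$elbow_deg,
                endpoint_x_m = s$kin$endpoint_xy[, 1],
                endpoint_y_m = s$kin$endpoint_xy[, 2]),
     "kinematics.csv")
  fw(data.frame(label = s$labels), "labels.csv")
  meta <- list(subject_id = s$subject_id,
               eeg = list(fs_hz = s$eeg$fs, t0_s = s$eeg$t0, unit = "uV",
                          channels = as.list(s$eeg$layout$names),
                          reference = s$eeg$layout$reference),
               kinematics = list(fs_hz = s$kin$fs, angle_unit = "deg",
                                 endpoint_unit = "m"),
               schedule = list(rest_lead_s = s$schedule$rest_lead_s))
  writeLines(yaml::as.yaml(meta), file.path(path, meta_filename))
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]. The EEG may alternatively be an EDF file
#' (`eeg.edf`, see [read_edf()]); kinematics sampled at a different rate
#' than the EEG (per the metadata sidecar) are linearly resampled onto
#' the EEG clock.
#'
#' @param path Session directory.
#' @return A validated [session_bundle()].
#' @export
read_session <- function(path) {
  need <- c("schedule.csv", "kinematics.csv", "labels.csv", meta_filename)
  have_csv <- file.exists(file.path(path, "eeg.csv"))
  have_edf <- file.exists(file.path(path, "eeg.edf"))
  missing <- c(need[!file.exists(file.path(path, need))],
               if (!have_csv && !have_edf) "eeg.csv")
  if (length(missing))
    stop("incomplete bundle: missing ", paste(missing, collapse = ", "))
  meta <- yaml::read_yaml(file.path(path, meta_filename))
  layout <- channel_layout(unlist(meta$eeg$channels),
                           meta$eeg$reference %||% "A2")
  if (have_csv) {
    eeg_dt <- data.table::fread(file.path(path, "eeg.csv"))
    if (!identical(names(eeg_dt), layout$names))
      stop("layout mismatch: eeg.csv channels differ from metadata")
    eeg <- eeg_recording(t(as.matrix(eeg_dt)), fs = meta$eeg$fs_hz,
                         layout = layout, t0 = meta$eeg$t0_s %||% 0)
  } else {
    eeg <- read_edf(file.path(path, "eeg.edf"))
    if (!identical(eeg$layout$names, layout$names))
      stop("layout mismatch: eeg.edf channels differ from metadata")
  }
  sched_dt <- data.table::fread(file.path(path, "schedule.csv"))
  if (nrow(sched_dt) > 1 && is.unsorted(sched_dt$time_s, strictly = TRUE))
    stop("clock error: schedule times not strictly increasing")
  schedule <- cue_schedule(as.data.frame(sched_dt),
                           rest_lead_s = meta$schedule$rest_lead_s %||% 10)
  kin_dt <- data.table::fread(file.path(path, "kinematics.csv"))
  kin <- kinematics_trace(meta$kinematics$fs_hz, kin_dt$shoulder_deg,
                          kin_dt$elbow_deg,
                          cbind(kin_dt$endpoint_x_m, kin_dt$endpoint_y_m))
  if (kin$fs != eeg$fs || length(kin$shoulder_deg) != ncol(eeg$data))
    kin <- resample_kinematics(kin, eeg$fs, n_out = ncol(eeg$data))
  labels <- data.table::fread(file.path(path, "labels.csv"))$label
  session_bundle(meta$subject_id, eeg, schedule, kin, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal EDF (16-bit) support ------------------------------------

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  substr(s, 1, width)
}

# ASCII numeric field of at most 8 characters
edf_num8 <- function(v) {
  s <- formatC(signif(v, 6), format = "g")
  ifelse(nchar(s) > 8, formatC(signif(v, 3), format = "g"), s)
}

#' Write an EEG recording as EDF
#'
#' Minimal European Data Format writer: one data record holding the whole
#' recording, 16-bit samples with per-channel physical scaling over the
#' data range. Lossy by quantisation (~1 part in 65k of the channel
#' range); use the delimited-text dialect when exact round-trips matter.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80), edf_pad("synthetic", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(1, 8), edf_pad(format(n / rec$fs, nsmall = 0), 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  fld <- function(vals, width) writeChar(
    paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
    con, eos = NULL)
  fld(rec$layout$names, 16)
  fld(rep("EEG", ns), 80)
  fld(rep("uV", ns), 8)
  pmin_ <- as.numeric(edf_num8(pmin_))   # store what the header will say
  pmax_ <- as.numeric(edf_num8(pmax_))
  fld(edf_num8(pmin_), 8)
  fld(edf_num8(pmax_), 8)
  fld(rep(-32768, ns), 8)
  fld(rep(32767, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(n, ns), 8)
  fld(rep("", ns), 32)
  for (i in seq_len(ns)) {
    dig <- round((rec$data[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                   65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Counterpart of [write_edf()]; handles standard multi-record EDF with a
#' uniform sampling rate across signals.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fldv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fldv(16)
  fldv(80); fldv(8)
  pmin_ <- as.numeric(fldv(8))
  pmax_ <- as.numeric(fldv(8))
  dmin_ <- as.numeric(fldv(8))
  dmax_ <- as.numeric(fldv(8))
  fldv(80)
  spr <- as.integer(fldv(8))  # samples per record, per signal
  fldv(32)
  data <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) for (i in seq_len(ns)) {
    dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
    phys <- pmin_[i] + (dig - dmin_[i]) / (dmax_[i] - dmin_[i]) *
      (pmax_[i] - pmin_[i])
    data[i, (r - 1) * spr[i] + seq_len(spr[i])] <- phys
  }
  fs <- spr[1] / rec_dur
  eeg_recording(data, fs = fs, layout = channel_layout(labels))
}
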