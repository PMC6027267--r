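#' @title Motion-related EEG features
#' @description Four per-sample feature families drive the intention
#'   classifier: slow-potential (MRCP) amplitude, delta band power, alpha
#'   band power, and running RMS. All are computed per channel on a
#'   CAR-corrected recording and keep the source length and sampling rate.
#' @name features
NULL

#' Construct a per-channel feature series
#'
#' @param kind Feature kind label (e.g. `"mrcp"`, `"alpha_power"`).
#' @param channel Channel label.
#' @param values Per-sample numeric series.
#' @param fs Sampling rate in Hz.
#' @return A `feature_series` object.
#' @export
feature_series <- function(kind, channel, values, fs) {
  structure(list(kind = kind, channel = channel,
                 values = as.numeric(values), fs = fs),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat("<feature_series> ", x$kind, " @ ", x$channel, ", ",
      length(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Slow cortical potential (MRCP) amplitude
#'
#' Movement-related cortical potentials appear as slow negative
#' deflections over motor cortex around movement preparation and onset.
#' The feature is the 0.1-2.0 Hz bandpassed amplitude (signed, microvolts)
#' of each channel.
#'
#' @param rec A CAR-corrected [eeg_recording()].
#' @param channels Optional channel subset (labels); default all.
#' @param mode Filtering mode, see [apply_filter()].
#' @return Named list of `feature_series`, one per channel.
#' @export
mrcp_amplitude <- function(rec, channels = NULL, mode = "zero_phase") {
  f <- filter_recording(rec, 0.1, 2.0, mode = mode, channels = channels)
  lapply(stats::setNames(nm = f$layout$names), function(ch)
    feature_series("mrcp", ch, f$data[ch, ], f$fs))
}

#' Delta or alpha band power
#'
#' The channel is bandpass filtered (delta 0.1-4.0 Hz, alpha 8-12 Hz) and
#' the filtered signal squared, giving an instantaneous power series in
#' squared microvolts.
#'
#' @param rec A CAR-corrected [eeg_recording()].
#' @param band `"delta"` or `"alpha"`.
#' @param channels Optional channel subset.
#' @param mode Filtering mode.
#' @return Named list of `feature_series`.
#' @export
band_power <- function(rec, band = c("delta", "alpha"), channels = NULL,
                       mode = "zero_phase") {
  band <- match.arg(band)
  edges <- if (band == "delta") c(0.1, 4.0) else c(8, 12)
  f <- filter_recording(rec, edges[1], edges[2], mode = mode,
                        channels = channels)
  kind <- paste0(band, "_power")
  lapply(stats::setNames(nm = f$layout$names), function(ch)
    feature_series(kind, ch, f$data[ch, ]^2, f$fs))
}

#' Running root-mean-square amplitude
#'
#' RMS over a trailing window of `window_ms` milliseconds ending at each
#' sample. The first samples, where a full window is not yet available,
#' use the shorter prefix. By default the signal is first bandpassed to
#' 0.1-4 Hz (the slow-activity band the other amplitude features live in);
#' set `prefilter = FALSE` to take the RMS of the raw channel.
#'
#' @param rec A CAR-corrected [eeg_recording()].
#' @param window_ms Trailing window length in ms (default 400; 100/200 are
#'   the other conventional choices).
#' @param channels Optional channel subset.
#' @param prefilter Bandpass 0.1-4 Hz before the RMS (default TRUE).
#' @param mode Filtering mode when `prefilter` is TRUE.
#' @return Named list of `feature_series`.
#' @export
rms_series <- function(rec, window_ms = 400, channels = NULL,
                       prefilter = TRUE, mode = "zero_phase") {
  stopifnot(inherits(rec, "eeg_recording"), window_ms > 0)
  na <- max(1L, as.integer(round(window_ms * rec$fs / 1000)))
  if (na > ncol(rec$data)) stop("window exceeds signal")
  src <- if (prefilter) filter_recording(rec, 0.1, 4.0, mode = mode,
                                         channels = channels)
         else if (is.null(channels)) rec
         else eeg_recording(rec$data[channels, , drop = FALSE], rec$fs,
                            channel_layout(channels, rec$layout$reference),
                            rec$t0)
  lapply(stats::setNames(nm = src$layout$names), function(ch)
    feature_series("rms", ch, running_rms(src$data[ch, ], na), src$fs))
}

running_rms <- function(x, na) {
  cs <- cumsum(x^2)
  n <- length(x)
  denom <- pmin(seq_len(n), na)
  lagged <- c(rep(0, na), cs[seq_len(n - na)])
  sqrt(pmax(cs - lagged, 0) / denom)
}

#' Rank channels by class discriminability
#'
#' Scores each channel's feature series by how well it separates either
#' movement class from rest: the absolute difference of class-conditional
#' means, divided by the pooled standard deviation, maximised over the two
#' movement classes. Channels are returned in decreasing score order
#' (ties broken alphabetically, so the ranking does not depend on input
#' order). An `override` bypasses scoring -- use it to pin the
#' conventional montage choices (FC2/C2 for slow-potential, RMS and delta
#' features; P3/Pz for alpha).
#'
#' @param series_by_channel Named list of `feature_series` of one kind.
#' @param labels Per-sample class series in `{-1, 0, +1}`, same length as
#'   the feature series.
#' @param k Number of channels to return (default 2).
#' @param override Optional label vector returned verbatim.
#' @return Ordered character vector of `k` channel labels.
#' @export
select_channels <- function(series_by_channel, labels, k = 2,
                            override = NULL) {
  if (!is.null(override)) return(as.character(override))
  chans <- vapply(series_by_channel, function(s) s$channel, "")
  if (k > length(chans)) stop("k exceeds channel count")
  lab <- as.numeric(labels)
  score <- vapply(series_by_channel, function(s) {
    v <- s$values
    if (length(v) != length(lab)) stop("series/label length mismatch")
    rest <- v[lab == 0]
    best <- 0
    for (cls in c(1, -1)) {
      g <- v[lab == cls]
      if (length(g) < 2 || length(rest) < 2) next
      pooled <- sqrt(((length(g) - 1) * stats::var(g) +
                      (length(rest) - 1) * stats::var(rest)) /
                     (length(g) + length(rest) - 2))
      if (pooled > 0)
        best <- max(best, abs(mean(g) - mean(rest)) / pooled)
    }
    best
  }, 0)
  ord <- order(-score, chans)
  unname(chans[ord][seq_len(k)])
}

#' Time-delayed feature matrix
#'
#' The classifier input: for each time sample `t` (with enough history),
#' the row is the concatenation over channels/series of
#' `(f(t), f(t - L), f(t - 2L))` where `L` is the lag in samples
#' (`lag_ms`, default 250 ms). The delayed copies let a static classifier
#' see the local dynamics of each feature.
#'
#' @param series List of `feature_series` (the selected channels, possibly
#'   several feature kinds), all aligned and sharing `fs`.
#' @param lag_ms Lag step in milliseconds (default 250).
#' @param n_lags Number of taps including lag zero (default 3).
#' @return A `feature_matrix`: list with the design matrix `X`
#'   (rows = usable time samples, columns = series x lags), `row_index`
#'   (1-based source sample index per row), `row_times` (seconds),
#'   `lag_samples`, `channels`, `kinds` and `fs`.
#' @export
build_feature_matrix <- function(series, lag_ms = 250, n_lags = 3) {
  if (inherits(series, "feature_series")) series <- list(series)
  fs <- series[[1]]$fs
  n <- length(series[[1]]$values)
  for (s in series) {
    if (s$fs != fs || length(s$values) != n)
      stop("series must be aligned with a common sampling rate")
  }
  l <- as.integer(round(lag_ms * fs / 1000))
  if (l < 1) stop("lag must be at least one sample")
  first <- (n_lags - 1L) * l + 1L
  if (n < first) stop("insufficient history")
  idx <- first:n
  cols <- list()
  nms <- character(0)
  for (s in series) {
    for (j in seq_len(n_lags) - 1L) {
      cols[[length(cols) + 1L]] <- s$values[idx - j * l]
      nms <- c(nms, sprintf("%s.%s.lag%d", s$kind, s$channel, j))
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- nms
  structure(list(X = x, row_index = idx, row_times = (idx - 1) / fs,
                 lag_samples = l,
                 channels = vapply(series, function(s) s$channel, ""),
                 kinds = unique(vapply(series, function(s) s$kind, "")),
                 fs = fs),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X), " rows x ", ncol(x$X),
      " cols; kinds ", paste(x$kinds, collapse = "+"),
      "; channels ", paste(unique(x$channels), collapse = ","),
      "; lag ", x$lag_samples, " samples\n", sep = "")
  invisible(x)
}

# thin rows of a feature matrix (and anything aligned to them)
decimate_feature_matrix <- function(fm, stride) {
  if (stride <= 1L) return(fm)
  keep <- seq(1L, nrow(fm$X), by = as.integer(stride))
  fm$X <- fm$X[keep, , drop = FALSE]
  fm$row_index <- fm$row_index[keep]
  fm$row_times <- fm$row_times[keep]
  fm
}
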