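#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean over all channels
#' from each channel. This suppresses noise common to the whole montage
#' and normalises the recording before feature extraction.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return An [eeg_recording()] of the same shape; channel means removed
#'   sample-wise, so the channel sum is zero at every sample.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stop("CAR undefined for N=1")
  out <- sweep(rec$data, 2, colMeans(rec$data))
  eeg_recording(out, fs = rec$fs, layout = rec$layout, t0 = rec$t0)
}

#' Design a linear-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) design. The tap count defaults to the smallest
#' odd integer of at least `3 * fs / low_hz`, which keeps the transition
#' band narrow relative to the lower edge -- the narrow-band 0.1-2 Hz
#' slow-potential filter therefore gets a long kernel, the 8-12 Hz alpha
#' filter a short one. Cutoffs follow the usual -6 dB-at-edge convention.
#'
#' @param low_hz,high_hz Passband edges in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Optional tap count override (made odd internally).
#' @return A `fir_filter_spec`: list with `low_hz`, `high_hz`, `order`
#'   (tap count) and `taps` (symmetric coefficients).
#' @export
design_fir_bandpass <- function(low_hz, high_hz, fs, order = NULL) {
  if (high_hz >= fs / 2) stop("band exceeds Nyquist")
  if (!(low_hz > 0 && low_hz < high_hz)) stop("invalid band edges")
  m <- if (is.null(order)) ceiling(3 * fs / low_hz) else as.integer(order)
  if (m %% 2 == 0) m <- m + 1L
  taps <- as.numeric(signal::fir1(m - 1L, c(low_hz, high_hz) / (fs / 2),
                                  type = "pass"))
  structure(list(low_hz = low_hz, high_hz = high_hz, order = m, taps = taps),
            class = "fir_filter_spec")
}

#' @export
print.fir_filter_spec <- function(x, ...) {
  cat("<fir_filter_spec> ", x$low_hz, "-", x$high_hz, " Hz bandpass, ",
      x$order, " taps\n", sep = "")
  invisible(x)
}

#' Complex frequency response of an FIR filter
#'
#' @param spec A `fir_filter_spec` (or bare tap vector).
#' @param freq_hz Frequencies at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex response values (take `abs()` for magnitude).
#' @export
fir_response <- function(spec, freq_hz, fs) {
  taps <- if (inherits(spec, "fir_filter_spec")) spec$taps else as.numeric(spec)
  k <- seq_along(taps) - 1
  vapply(freq_hz,
         function(f) sum(taps * exp(-2i * pi * f * k / fs)),
         complex(1))
}

#' Apply an FIR filter to a sample series
#'
#' `causal` mode is the plain convolution `y[n] = sum_k b_k x[n-k]` with a
#' zero-padded history, as a real-time controller would run it.
#' `zero_phase` applies the (symmetric) kernel twice with the group delay
#' compensated, giving the squared magnitude response and no lag; the
#' series is reflect-padded by one kernel length beforehand and trimmed
#' after, which suppresses startup transients of long low-frequency
#' kernels. Offline analysis uses `zero_phase`.
#'
#' @param x Numeric sample series, longer than three kernel lengths.
#' @param spec A `fir_filter_spec` (or bare tap vector).
#' @param mode `"zero_phase"` (default) or `"causal"`.
#' @return Filtered series, same length as `x`.
#' @export
apply_filter <- function(x, spec, mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  taps <- if (inherits(spec, "fir_filter_spec")) spec$taps else as.numeric(spec)
  n <- length(x)
  m <- length(taps)
  if (m > 1 && n <= 3 * m) stop("signal shorter than filter")
  if (mode == "causal") return(fft_fir(taps, x))
  if (m %% 2 == 0) stop("zero_phase mode requires an odd tap count")
  d <- (m - 1L) %/% 2L
  p <- min(m, n - 1L)
  xp <- c(rev(x[2:(p + 1L)]), x, rev(x[(n - p):(n - 1L)]))
  one_pass <- function(v) {
    if (d == 0L) return(fft_fir(taps, v))
    y <- fft_fir(taps, c(v, numeric(d)))
    y[-seq_len(d)]
  }
  z <- one_pass(one_pass(xp))
  z[(p + 1L):(p + n)]
}

# overlap-free FFT convolution; returns the first length(x) samples,
# i.e. causal filtering with zero initial history
fft_fir <- function(taps, x) {
  if (length(taps) == 1L) return(taps * x)
  as.numeric(signal::fftfilt(taps, x))
}

#' Bandpass-filter every channel of a recording
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Band edges in Hz.
#' @param mode Filtering mode, see [apply_filter()].
#' @param channels Optional subset of channel labels to keep (filters only
#'   those, returning a smaller recording).
#' @return An [eeg_recording()] with filtered data.
#' @export
filter_recording <- function(rec, low_hz, high_hz,
                             mode = "zero_phase", channels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  # cap the kernel at a third of the recording so short sessions remain
  # filterable; long kernels only matter for the 0.1 Hz edge anyway
  cap <- (ncol(rec$data) - 1L) %/% 3L
  if (cap %% 2L == 0L) cap <- cap - 1L
  want <- ceiling(3 * rec$fs / low_hz)
  spec <- design_fir_bandpass(low_hz, high_hz, rec$fs,
                              order = min(want + 1 - want %% 2, cap))
  keep <- if (is.null(channels)) rec$layout$names else as.character(channels)
  miss <- setdiff(keep, rec$layout$names)
  if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
  out <- t(apply(rec$data[keep, , drop = FALSE], 1, apply_filter,
                 spec = spec, mode = mode))
  eeg_recording(out, fs = rec$fs,
                layout = channel_layout(keep, rec$layout$reference),
                t0 = rec$t0)
}
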