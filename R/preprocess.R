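#' Zero-phase filtering with odd-reflection edge padding
#'
#' signal::filtfilt alone leaves visible end transients for cutoffs far
#' below Nyquist; reflecting the signal about its end points before
#' filtering suppresses them.
#' @noRd
zeroPhaseFilter <- function(flt, x, padLength) {
  n <- length(x)
  L <- max(1, min(n - 1, padLength))
  head <- 2 * x[1] - x[(L + 1):2]
  tail <- 2 * x[n] - x[(n - 1):(n - L)]
  y <- signal::filtfilt(flt, c(head, x, tail))
  y[(L + 1):(L + n)]
}

#' Low-pass filter one channel
#'
#' Butterworth low-pass (default 4th order) applied forward-backward
#' (zero phase) with odd-reflection edge padding, so the output has the
#' same length as the input, no phase shift, and passband gain ~ 1.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param spec a [FilterSpec-class]; `spec@cutoff` must be below the
#'   Nyquist frequency.
#' @return filtered vector, same length as `x`.
#' @examples
#' fs <- 250
#' t <- seq(0, 2, by = 1 / fs)
#' y <- lowpassFilter(sin(2 * pi * 1 * t), fs, filterSpec())
#' @export
lowpassFilter <- function(x, fs, spec = filterSpec()) {
  stopifnot(is(spec, "FilterSpec"))
  validObject(spec)
  if (spec@cutoff >= fs / 2)
    stop("low-pass cutoff (", spec@cutoff, " Hz) must be below Nyquist (",
         fs / 2, " Hz)")
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  if (length(x) <= 3 * spec@order)
    stop("signal too short for a stable order-", spec@order, " filter")
  bf <- signal::butter(spec@order, spec@cutoff / (fs / 2), type = "low")
  pad <- ceiling(6 * fs / spec@cutoff)
  if (spec@zeroPhase) {
    zeroPhaseFilter(bf, x, pad)
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Median despiking filter
#'
#' Running median over a kernel of `spec@medianKernel` seconds
#' (converted to an odd sample count >= 3). Impulsive artifacts
#' narrower than half the kernel, such as maternal-ECG spikes, are
#' removed; slow EHG waves pass essentially unchanged.
#'
#' @inheritParams lowpassFilter
#' @return despiked vector, same length as `x`.
#' @export
medianDespike <- function(x, fs, spec = filterSpec()) {
  stopifnot(is(spec, "FilterSpec"))
  k <- round(spec@medianKernel * fs)
  if (k %% 2 == 0) k <- k + 1
  k <- max(k, 3)
  if (k >= length(x))
    stop("median kernel (", k, " samples) must be shorter than the signal (",
         length(x), " samples)")
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

#' Normalize amplitude to [-1, 1]
#'
#' Sign-preserving linear scaling `x / max(|x|)`, applied per channel
#' over the full preprocessed recording (not per segment), so the
#' largest excursion maps to +/-1. Idempotent.
#'
#' @param x numeric sample vector; must not be all zero.
#' @return scaled vector with `max(abs(.)) == 1`.
#' @examples
#' normalizeAmplitude(c(-2, 0, 1))  # -1, 0, 0.5
#' @export
normalizeAmplitude <- function(x) {
  m <- max(abs(x))
  if (m == 0) stop("cannot normalize an all-zero signal (undefined scale)")
  if (length(unique(x)) == 1)
    warning("constant signal normalizes to +/-1")
  x / m
}

#' Preprocess a recording
#'
#' Fixed pipeline per channel: low-pass (default 0-3 Hz, zero phase)
#' then median despiking, retaining the un-normalized result, then
#' per-channel amplitude normalization to [-1, 1] over the whole
#' recording. Both variants are kept because downstream waveform
#' characteristics are extracted from each.
#'
#' @param recording an [EHGRecording-class].
#' @param spec a [FilterSpec-class].
#' @return a [PreprocessedRecording-class].
#' @examples
#' rec <- generateRecording(recordingConfig(duration = 400,
#'                                          nContractions = 1,
#'                                          nChannels = 2, seed = 5))
#' pre <- preprocessRecording(rec)
#' pre
#' @export
preprocessRecording <- function(recording, spec = filterSpec()) {
  stopifnot(is(recording, "EHGRecording"))
  ehg <- ehgSignals(recording)
  fs <- samplingRate(recording)
  filtered <- t(apply(ehg, 1, function(ch)
    medianDespike(lowpassFilter(ch, fs, spec), fs, spec)))
  normalized <- t(apply(filtered, 1, normalizeAmplitude))
  new("PreprocessedRecording",
      filtered = filtered, normalized = normalized,
      toco = tocoSignal(recording), samplingRate = fs,
      annotations = annotations(recording), filterSpec = spec)
}
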