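#' Band-limited Gaussian noise via FFT spectral shaping
#'
#' White Gaussian noise whose spectrum is restricted to [lo, hi] Hz and
#' rescaled to unit standard deviation. With `knee` finite, the in-band
#' amplitude falls off as a Lorentzian 1/sqrt(1 + (f/knee)^2),
#' mimicking the steep low-frequency concentration of surface EHG;
#' `knee = Inf` gives a flat band. FFT shaping avoids the numerical
#' instability of very-low-frequency IIR bandpass designs and is
#' exactly reproducible.
#' @noRd
bandNoise <- function(n, fs, lo, hi, knee = Inf) {
  x <- stats::rnorm(n)
  if (n < 4) return(x)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k) * fs / n        # symmetric (two-sided) frequency
  gain <- as.numeric(freq >= lo & freq <= hi)
  if (is.finite(knee)) gain <- gain / sqrt(1 + (freq / knee)^2)
  X <- X * gain
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(rep(0, n))
  y / s
}

#' Hann envelope of a given sample length, peak 1
#' @noRd
hannEnvelope <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Draw a feasible contraction schedule
#' @noRd
scheduleContractions <- function(config) {
  k <- config@nContractions
  if (k == 0) return(data.frame(start = numeric(), end = numeric()))
  dur <- stats::runif(k, config@contractionDurationRange[1],
                      config@contractionDurationRange[2])
  gap <- stats::runif(k, config@interContractionGapRange[1],
                      config@interContractionGapRange[2])
  # first gap doubles as the lead-in before the first contraction,
  # shortened so short recordings remain usable
  start <- cumsum(c(gap[1] / 3, if (k > 1) gap[-1] else numeric())) +
    cumsum(c(0, if (k > 1) dur[-k] else numeric()))
  end <- start + dur
  if (end[k] > config@duration)
    stop("infeasible contraction schedule: ", k,
         " contractions with the configured durations and gaps need ",
         round(end[k], 1), " s but the recording lasts ",
         config@duration, " s")
  data.frame(start = start, end = end)
}

#' Add EHG artifacts to a clean signal
#'
#' Adds the three contaminants that preprocessing is expected to
#' suppress: (i) very-low-frequency baseline drift (< 0.05 Hz, from
#' low-pass-filtered white noise), (ii) a 50 Hz powerline sinusoid with
#' random phase, and (iii) periodic biphasic maternal-ECG-like spikes
#' at `mecgRate` Hz. With all artifact amplitudes zero the input is
#' returned unchanged. Consumes the current RNG stream; inside
#' [generateRecording()] this is covered by the configuration seed.
#'
#' @param clean numeric vector (one channel) or matrix (channels x
#'   samples).
#' @param config a [RecordingConfig-class] providing the amplitudes,
#'   the mECG rate and the sampling rate.
#' @return object of the same shape as `clean`.
#' @export
addArtifacts <- function(clean, config) {
  stopifnot(is(config, "RecordingConfig"))
  if (config@baselineDriftAmplitude == 0 && config@powerlineAmplitude == 0 &&
      config@mecgAmplitude == 0)
    return(clean)
  if (is.matrix(clean)) {
    out <- clean
    for (i in seq_len(nrow(clean)))
      out[i, ] <- addArtifacts(clean[i, ], config)
    return(out)
  }
  fs <- config@samplingRate
  n <- length(clean)
  out <- clean
  if (config@baselineDriftAmplitude > 0) {
    drift <- bandNoise(n, fs, 0, 0.05)
    out <- out + config@baselineDriftAmplitude * drift
  }
  if (config@powerlineAmplitude > 0) {
    t <- (seq_len(n) - 1) / fs
    out <- out + config@powerlineAmplitude *
      sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
  }
  if (config@mecgAmplitude > 0) {
    width <- max(4, round(0.04 * fs))          # ~40 ms biphasic complex
    spike <- sin(2 * pi * (seq_len(width) - 1) / width)
    onset <- round((seq(0, by = 1 / config@mecgRate,
                        length.out = floor(n / fs * config@mecgRate)) + 0.1) * fs)
    for (s in onset) {
      idx <- (s + 1):(s + width)
      idx <- idx[idx <= n]
      if (length(idx))
        out[idx] <- out[idx] + config@mecgAmplitude * spike[seq_along(idx)]
    }
  }
  out
}

#' Generate a synthetic multichannel EHG recording
#'
#' Simulates one monitoring session according to a
#' [RecordingConfig-class]: each channel is baseline colored noise
#' (band-limited to 0.1-3 Hz, unit variance) plus, during each planted
#' contraction, an amplitude-modulated band-limited noise burst under a
#' smooth Hann envelope, then artifacts. The burst amplitude is set so
#' the mean in-band power inside a contraction is
#' `contractionPowerGain` times the baseline in-band power;
#' `contractionRegularity` narrows the burst band from 0.1-3 Hz (0,
#' same character as baseline) towards 0.3-0.8 Hz (1, strongly
#' narrowband, hence lower sample entropy). Channels receive a random
#' overall gain; `bestChannel` additionally receives
#' `bestChannelBoost` on its burst amplitude, emulating the electrode
#' best coupled to the active uterine region. The TOCO-like reference
#' is the summed burst envelope plus a little noise, low-passed at
#' 0.1 Hz and clipped at zero.
#'
#' Generation is deterministic for a fixed configuration (including
#' seed).
#'
#' @param config a [RecordingConfig-class].
#' @return an [EHGRecording-class] with annotations matching the
#'   planted bursts exactly.
#' @examples
#' rec <- generateRecording(recordingConfig(duration = 600,
#'                                          nContractions = 2,
#'                                          nChannels = 2, seed = 3))
#' rec
#' annotations(rec)
#' @export
generateRecording <- function(config) {
  stopifnot(is(config, "RecordingConfig"))
  validObject(config)
  set.seed(config@seed)
  fs <- config@samplingRate
  n <- round(config@duration * fs)
  sched <- scheduleContractions(config)
  nc <- config@nChannels

  # burst band narrows with regularity
  reg <- config@contractionRegularity
  burstLo <- 0.1 + 0.2 * reg
  burstHi <- 3.0 - 2.2 * reg
  # mean Hann^2 is 3/8: amplitude such that mean in-burst added power
  # equals (gain - 1) x baseline in-band power (which is 1)
  gain <- config@contractionPowerGain
  burstAmp <- if (gain > 1) sqrt((gain - 1) / 0.375) else 0

  chGain <- stats::runif(nc, config@channelGainRange[1],
                         config@channelGainRange[2])

  envSum <- numeric(n)
  ehg <- matrix(0, nrow = nc, ncol = n)
  for (ci in seq_len(nc)) {
    x <- bandNoise(n, fs, 0.1, 3, knee = 0.5)
    if (nrow(sched) && burstAmp > 0) {
      boost <- if (ci == config@bestChannel) config@bestChannelBoost else 1
      for (k in seq_len(nrow(sched))) {
        i0 <- round(sched$start[k] * fs) + 1
        i1 <- round(sched$end[k] * fs)
        len <- i1 - i0 + 1
        env <- hannEnvelope(len)
        carrier <- bandNoise(len, fs, burstLo, burstHi, knee = 0.5)
        x[i0:i1] <- x[i0:i1] + burstAmp * boost * env * carrier
        if (ci == 1) envSum[i0:i1] <- envSum[i0:i1] + env
      }
    } else if (ci == 1 && nrow(sched)) {
      for (k in seq_len(nrow(sched))) {
        i0 <- round(sched$start[k] * fs) + 1
        i1 <- round(sched$end[k] * fs)
        envSum[i0:i1] <- envSum[i0:i1] + hannEnvelope(i1 - i0 + 1)
      }
    }
    if (config@baselineModulation > 0) {
      # slow multiplicative nonstationarity of the EHG content
      x <- x * exp(config@baselineModulation * bandNoise(n, fs, 0, 0.005))
    }
    ehg[ci, ] <- chGain[ci] * x
  }
  ehg <- addArtifacts(ehg, config)

  toco <- envSum + 0.05 * stats::rnorm(n)
  if (n > 12) {
    bf <- signal::butter(2, min(0.1 / (fs / 2), 0.99), type = "low")
    toco <- zeroPhaseFilter(bf, toco, padLength = min(n - 1, round(10 * fs)))
  }
  toco <- pmax(toco, 0)

  new("EHGRecording", ehg = ehg, toco = toco, samplingRate = fs,
      annotations = sched, config = config)
}
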