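#' Create a synthetic-recording configuration
#'
#' Defaults emulate one pre-delivery monitoring session: 250 Hz, 8
#' abdominal EHG channels, contractions of 30-60 s separated by
#' 90-180 s of quiescence, a doubling of in-band (0.1-3 Hz) EHG power
#' during contractions, markedly more regular (narrowband) burst
#' activity, one best-coupled electrode, and realistic baseline drift,
#' 50 Hz interference and maternal-ECG spikes. Amplitudes are in
#' arbitrary units relative to a baseline EHG standard deviation of 1;
#' real EHG has no canonical amplitude scale.
#'
#' @param samplingRate sampling rate in Hz.
#' @param nChannels number of EHG channels.
#' @param duration recording duration in seconds.
#' @param nContractions number of contractions to plant.
#' @param contractionDurationRange contraction duration range (s).
#' @param interContractionGapRange gap range between contractions (s).
#' @param contractionPowerGain in-band power ratio contraction/baseline
#'   (>= 1; 1 plants no power signal).
#' @param contractionRegularity burst regularity in [0, 1]; larger
#'   values narrow the burst band towards 0.3-0.8 Hz, lowering the
#'   sample entropy of contraction segments.
#' @param channelGainRange whole-channel amplitude gain range.
#' @param bestChannel channel receiving a burst boost (0 = none).
#' @param bestChannelBoost burst amplitude multiplier for that channel.
#' @param baselineModulation SD of the slow log-amplitude modulation
#'   of each channel's EHG content (< 0.005 Hz), emulating the
#'   nonstationary electrode coupling and background tone of real
#'   abdominal recordings; amplitude features inherit this variability
#'   while scale-invariant characteristics do not.
#' @param baselineDriftAmplitude drift amplitude (< 0.05 Hz component).
#' @param powerlineAmplitude 50 Hz interference amplitude.
#' @param mecgAmplitude maternal-ECG spike amplitude.
#' @param mecgRate maternal-ECG spike rate (Hz).
#' @param seed integer seed for deterministic generation.
#' @return a validated [RecordingConfig-class] object.
#' @examples
#' cfg <- recordingConfig(duration = 600, nContractions = 2, seed = 7)
#' cfg
#' @export
recordingConfig <- function(samplingRate = 250, nChannels = 8,
                            duration = 900, nContractions = 4,
                            contractionDurationRange = c(30, 60),
                            interContractionGapRange = c(90, 180),
                            contractionPowerGain = 2,
                            contractionRegularity = 0.8,
                            channelGainRange = c(0.7, 1.3),
                            bestChannel = 1, bestChannelBoost = 1.5,
                            baselineModulation = 0.4,
                            baselineDriftAmplitude = 0.5,
                            powerlineAmplitude = 0.5,
                            mecgAmplitude = 2, mecgRate = 1.2,
                            seed = 1) {
  new("RecordingConfig",
      samplingRate = samplingRate, nChannels = nChannels,
      duration = duration, nContractions = nContractions,
      contractionDurationRange = as.numeric(contractionDurationRange),
      interContractionGapRange = as.numeric(interContractionGapRange),
      contractionPowerGain = contractionPowerGain,
      contractionRegularity = contractionRegularity,
      channelGainRange = as.numeric(channelGainRange),
      bestChannel = bestChannel, bestChannelBoost = bestChannelBoost,
      baselineModulation = baselineModulation,
      baselineDriftAmplitude = baselineDriftAmplitude,
      powerlineAmplitude = powerlineAmplitude,
      mecgAmplitude = mecgAmplitude, mecgRate = mecgRate,
      seed = seed)
}

#' Create a filter specification
#'
#' @param cutoff low-pass cutoff in Hz.
#' @param order Butterworth order.
#' @param zeroPhase apply forward-backward (zero phase).
#' @param medianKernel median filter kernel in seconds.
#' @return a [FilterSpec-class] object.
#' @export
filterSpec <- function(cutoff = 3, order = 4, zeroPhase = TRUE,
                       medianKernel = 0.3) {
  new("FilterSpec", cutoff = cutoff, order = order,
      zeroPhase = zeroPhase, medianKernel = medianKernel)
}

#' Create sample-entropy parameters
#'
#' @param m template length.
#' @param nTarget resampled segment length (`NA` keeps the raw length).
#' @param rStrategy tolerance strategy, `"std_fraction"` or
#'   `"autocorr_zero_cross"`.
#' @param rFraction tolerance scale factor.
#' @return a [SamEnParams-class] object.
#' @export
samEnParams <- function(m = 8, nTarget = 500,
                        rStrategy = c("std_fraction", "autocorr_zero_cross"),
                        rFraction = 0.2) {
  new("SamEnParams", m = m, nTarget = as.numeric(nTarget),
      rStrategy = match.arg(rStrategy), rFraction = rFraction)
}

#' Create Lyapunov-estimator parameters
#'
#' @param embeddingDim embedding dimension.
#' @param delay embedding delay (samples).
#' @param theiler Theiler exclusion window (samples).
#' @param kMax maximum divergence horizon (steps).
#' @param fitRange explicit fit range (step pair) or `NULL` for
#'   automatic detection of the initial linear region.
#' @param resampleLength resampled segment length (`NA` keeps raw).
#' @return a [LyapunovParams-class] object.
#' @export
lyapunovParams <- function(embeddingDim = 5, delay = 1, theiler = 10,
                           kMax = 30, fitRange = NULL,
                           resampleLength = 500) {
  new("LyapunovParams", embeddingDim = embeddingDim, delay = delay,
      theiler = theiler, kMax = kMax,
      fitRange = if (is.null(fitRange)) NULL else as.numeric(fitRange),
      resampleLength = as.numeric(resampleLength))
}

#' Create CART training parameters
#'
#' @param minSamplesLeaf minimum observations per leaf.
#' @param maxDepth maximum depth.
#' @param innerFolds inner CV folds for best-level pruning.
#' @return a [TreeParams-class] object.
#' @export
treeParams <- function(minSamplesLeaf = 5, maxDepth = 30, innerFolds = 10) {
  new("TreeParams", splitCriterion = "gini",
      minSamplesLeaf = minSamplesLeaf, maxDepth = maxDepth,
      innerFolds = innerFolds)
}
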