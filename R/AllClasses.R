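#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Recording configuration for the synthetic EHG generator
#'
#' Describes one synthetic recording session: sampling rate, channel
#' count, contraction schedule, the planted class-discriminating
#' structure (in-band power gain and burst regularity), channel
#' heterogeneity and artifact levels. Amplitudes are in arbitrary
#' units relative to a baseline EHG standard deviation of 1.
#'
#' @slot samplingRate sampling rate in Hz.
#' @slot nChannels number of EHG channels.
#' @slot duration recording length in seconds.
#' @slot nContractions number of contractions to plant.
#' @slot contractionDurationRange min/max contraction duration (s).
#' @slot interContractionGapRange min/max gap between contractions (s).
#' @slot contractionPowerGain ratio (>= 1) of in-band (0.1-3 Hz) EHG
#'   power inside a contraction to the baseline in-band power.
#' @slot contractionRegularity value in [0, 1]; 0 keeps the burst
#'   spectrally identical to baseline, 1 makes it strongly narrowband
#'   (0.3-0.8 Hz), lowering its sample entropy.
#' @slot channelGainRange per-channel multiplicative amplitude gain
#'   range (applied to the whole channel, artifacts included).
#' @slot bestChannel index of the channel whose bursts receive an
#'   extra amplitude boost, emulating an electrode placed over the
#'   most active uterine region; 0 disables it.
#' @slot bestChannelBoost burst amplitude multiplier for `bestChannel`.
#' @slot baselineModulation standard deviation of the slow (< 0.005 Hz)
#'   log-amplitude modulation of each channel's EHG content, emulating
#'   electrode-coupling and background-tone nonstationarity; 0 disables
#'   it.
#' @slot baselineDriftAmplitude amplitude of the < 0.05 Hz drift.
#' @slot powerlineAmplitude amplitude of the 50 Hz interference.
#' @slot mecgAmplitude amplitude of the maternal-ECG-like spikes.
#' @slot mecgRate spike rate in Hz.
#' @slot seed integer seed; generation is deterministic given the
#'   configuration.
#' @seealso [recordingConfig()], [generateRecording()]
#' @exportClass RecordingConfig
setClass("RecordingConfig",
  representation(
    samplingRate = "numeric",
    nChannels = "numeric",
    duration = "numeric",
    nContractions = "numeric",
    contractionDurationRange = "numeric",
    interContractionGapRange = "numeric",
    contractionPowerGain = "numeric",
    contractionRegularity = "numeric",
    channelGainRange = "numeric",
    bestChannel = "numeric",
    bestChannelBoost = "numeric",
    baselineModulation = "numeric",
    baselineDriftAmplitude = "numeric",
    powerlineAmplitude = "numeric",
    mecgAmplitude = "numeric",
    mecgRate = "numeric",
    seed = "numeric"
  )
)

setValidity("RecordingConfig", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (object@nChannels < 1) msg <- c(msg, "nChannels must be >= 1")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@nContractions < 0) msg <- c(msg, "nContractions must be >= 0")
  if (length(object@contractionDurationRange) != 2 ||
      any(object@contractionDurationRange <= 0) ||
      diff(object@contractionDurationRange) < 0)
    msg <- c(msg, "contractionDurationRange must be an increasing positive pair")
  if (length(object@interContractionGapRange) != 2 ||
      any(object@interContractionGapRange <= 0) ||
      diff(object@interContractionGapRange) < 0)
    msg <- c(msg, "interContractionGapRange must be an increasing positive pair")
  if (object@contractionPowerGain < 1)
    msg <- c(msg, "contractionPowerGain must be >= 1")
  if (object@contractionRegularity < 0 || object@contractionRegularity > 1)
    msg <- c(msg, "contractionRegularity must lie in [0, 1]")
  if (length(object@channelGainRange) != 2 ||
      any(object@channelGainRange <= 0))
    msg <- c(msg, "channelGainRange must be a positive pair")
  if (object@bestChannel != 0 &&
      (object@bestChannel < 1 || object@bestChannel > object@nChannels))
    msg <- c(msg, "bestChannel must be 0 or a valid channel index")
  if (object@bestChannelBoost <= 0) msg <- c(msg, "bestChannelBoost must be > 0")
  if (object@baselineModulation < 0)
    msg <- c(msg, "baselineModulation must be >= 0")
  if (object@baselineDriftAmplitude < 0 || object@powerlineAmplitude < 0 ||
      object@mecgAmplitude < 0)
    msg <- c(msg, "artifact amplitudes must be >= 0")
  if (object@mecgRate <= 0) msg <- c(msg, "mecgRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' A synthetic or imported multichannel EHG recording
#'
#' Holds the raw EHG channel matrix, a nonnegative TOCO-like reference
#' trace, the sampling rate, contraction annotations (ground truth by
#' construction for synthetic data) and an echo of the generating
#' configuration. The TOCO trace is a human-readable timing reference
#' only; it never enters classification.
#'
#' @slot ehg numeric matrix, channels in rows, samples in columns.
#' @slot toco numeric vector, same number of samples, >= 0 everywhere.
#' @slot samplingRate Hz.
#' @slot annotations data.frame with columns `start`, `end` (seconds).
#' @slot config the [RecordingConfig-class] used for generation.
#' @exportClass EHGRecording
setClass("EHGRecording",
  representation(
    ehg = "matrix",
    toco = "numeric",
    samplingRate = "numeric",
    annotations = "data.frame",
    config = "RecordingConfig"
  )
)

setValidity("EHGRecording", function(object) {
  msg <- character()
  if (length(object@toco) != ncol(object@ehg))
    msg <- c(msg, "toco length must equal number of samples")
  if (any(object@toco < 0)) msg <- c(msg, "toco must be nonnegative")
  if (!all(c("start", "end") %in% names(object@annotations)))
    msg <- c(msg, "annotations need 'start' and 'end' columns")
  else {
    a <- object@annotations
    if (nrow(a) && any(a$end <= a$start))
      msg <- c(msg, "annotation end must exceed start")
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)]))
      msg <- c(msg, "annotations must be disjoint and sorted")
    if (nrow(a) && (any(a$start < 0) ||
        any(a$end > ncol(object@ehg) / object@samplingRate + 1e-9)))
      msg <- c(msg, "annotations must lie inside the recording")
  }
  if (length(msg)) msg else TRUE
})

#' Low-pass / median filter specification
#'
#' @slot cutoff low-pass cutoff in Hz (default 3).
#' @slot order Butterworth order (default 4, applied forward-backward).
#' @slot zeroPhase logical; apply the filter forward-backward.
#' @slot medianKernel median filter kernel length in seconds; it is
#'   converted to an odd sample count >= 3.
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(cutoff = "numeric", order = "numeric",
                 zeroPhase = "logical", medianKernel = "numeric")
)

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (object@cutoff <= 0) msg <- c(msg, "cutoff must be > 0")
  if (object@order < 1) msg <- c(msg, "order must be >= 1")
  if (object@medianKernel <= 0) msg <- c(msg, "medianKernel must be > 0")
  if (length(msg)) msg else TRUE
})

#' A preprocessed recording (filtered and normalized variants)
#'
#' Produced by [preprocessRecording()]. Carries the low-pass +
#' median-filtered EHG matrix and its per-channel amplitude-normalized
#' counterpart (each channel scaled to max |x| = 1 over the whole
#' recording), plus the annotations needed for segmentation.
#'
#' @slot filtered filtered (un-normalized) channel matrix.
#' @slot normalized per-channel normalized channel matrix.
#' @slot toco TOCO reference copied from the source recording.
#' @slot samplingRate Hz.
#' @slot annotations contraction annotations (seconds).
#' @slot filterSpec the [FilterSpec-class] applied.
#' @exportClass PreprocessedRecording
setClass("PreprocessedRecording",
  representation(
    filtered = "matrix",
    normalized = "matrix",
    toco = "numeric",
    samplingRate = "numeric",
    annotations = "data.frame",
    filterSpec = "FilterSpec"
  )
)

setValidity("PreprocessedRecording", function(object) {
  if (!identical(dim(object@filtered), dim(object@normalized)))
    return("filtered and normalized matrices must have identical shape")
  TRUE
})

#' A set of labelled contraction / non-contraction segments
#'
#' One row of `info` per (channel, window) pair; the parallel lists
#' `unnormalized` and `normalized` hold the sample vectors cut from the
#' two preprocessed signal variants. Windows dropped because the
#' trailing non-contraction interval collided with the next contraction
#' or the end of the recording are logged in `dropped`.
#'
#' @slot info data.frame with columns segment_id, channel, label,
#'   start, end (seconds).
#' @slot unnormalized list of numeric sample vectors.
#' @slot normalized list of numeric sample vectors.
#' @slot samplingRate Hz.
#' @slot dropped character log of dropped windows.
#' @exportClass SegmentSet
setClass("SegmentSet",
  representation(
    info = "data.frame",
    unnormalized = "list",
    normalized = "list",
    samplingRate = "numeric",
    dropped = "character"
  )
)

setValidity("SegmentSet", function(object) {
  msg <- character()
  if (length(object@unnormalized) != nrow(object@info) ||
      length(object@normalized) != nrow(object@info))
    msg <- c(msg, "sample lists must parallel the info table")
  if (nrow(object@info) &&
      !all(object@info$label %in% c("contraction", "non_contraction")))
    msg <- c(msg, "labels must be 'contraction' or 'non_contraction'")
  ok <- mapply(function(a, b) length(a) == length(b),
               object@unnormalized, object@normalized)
  if (length(ok) && !all(ok))
    msg <- c(msg, "paired sample vectors must have equal length")
  if (length(msg)) msg else TRUE
})

#' Sample entropy parameters
#'
#' @slot m template length (default 8).
#' @slot nTarget length the segment is resampled to before template
#'   matching (default 500); `NA` disables resampling.
#' @slot rStrategy `"std_fraction"` (r = rFraction * SD of the
#'   resampled segment, scale-invariant) or `"autocorr_zero_cross"`
#'   (r = rFraction * SD of the lag-L increment sequence, with L the
#'   first zero-crossing lag of the autocorrelation).
#' @slot rFraction tolerance scale factor (default 0.2).
#' @exportClass SamEnParams
setClass("SamEnParams",
  representation(m = "numeric", nTarget = "numeric",
                 rStrategy = "character", rFraction = "numeric")
)

setValidity("SamEnParams", function(object) {
  msg <- character()
  if (object@m < 1) msg <- c(msg, "m must be >= 1")
  if (!is.na(object@nTarget) && object@nTarget <= object@m + 1)
    msg <- c(msg, "nTarget must exceed m + 1")
  if (!object@rStrategy %in% c("std_fraction", "autocorr_zero_cross"))
    msg <- c(msg, "unknown rStrategy")
  if (object@rFraction <= 0) msg <- c(msg, "rFraction must be > 0")
  if (length(msg)) msg else TRUE
})

#' Largest-Lyapunov-exponent (Rosenstein) parameters
#'
#' @slot embeddingDim delay-embedding dimension (default 5).
#' @slot delay embedding delay in samples (default 1).
#' @slot theiler Theiler window excluding temporal neighbours from the
#'   nearest-neighbour search (default 10 samples).
#' @slot kMax maximum divergence horizon in steps (default 30).
#' @slot fitRange integer pair of divergence steps to fit the slope
#'   over, or `NULL` for automatic linear-region detection.
#' @slot resampleLength length the segment is resampled to (default
#'   500); `NA` disables resampling.
#' @exportClass LyapunovParams
setClass("LyapunovParams",
  representation(embeddingDim = "numeric", delay = "numeric",
                 theiler = "numeric", kMax = "numeric",
                 fitRange = "numericOrNULL", resampleLength = "numeric")
)

setValidity("LyapunovParams", function(object) {
  msg <- character()
  if (object@embeddingDim < 2) msg <- c(msg, "embeddingDim must be >= 2")
  if (object@delay < 1) msg <- c(msg, "delay must be >= 1")
  if (!is.null(object@fitRange) && length(object@fitRange) != 2)
    msg <- c(msg, "fitRange must be NULL or a length-2 vector")
  if (length(msg)) msg else TRUE
})

#' CART training parameters
#'
#' @slot splitCriterion only `"gini"` is supported.
#' @slot minSamplesLeaf minimum observations per leaf (default 5).
#' @slot maxDepth maximum tree depth (default 30, rpart's ceiling).
#' @slot innerFolds inner cross-validation folds used to choose the
#'   best pruning level (default 10).
#' @exportClass TreeParams
setClass("TreeParams",
  representation(splitCriterion = "character", minSamplesLeaf = "numeric",
                 maxDepth = "numeric", innerFolds = "numeric")
)

setValidity("TreeParams", function(object) {
  msg <- character()
  if (!identical(object@splitCriterion, "gini"))
    msg <- c(msg, "splitCriterion must be 'gini'")
  if (object@minSamplesLeaf < 1) msg <- c(msg, "minSamplesLeaf must be >= 1")
  if (object@innerFolds < 2) msg <- c(msg, "innerFolds must be >= 2")
  if (length(msg)) msg else TRUE
})
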