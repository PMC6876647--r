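#' Accessors for recordings, preprocessed recordings and segment sets
#'
#' Small generic accessors so downstream code never touches slots
#' directly: sampling rate, contraction annotations, channel count,
#' the EHG channel matrix, the TOCO reference trace, the segment info
#' table and the log of dropped windows.
#'
#' @param object an [EHGRecording-class], [PreprocessedRecording-class]
#'   or [SegmentSet-class] object, as applicable.
#' @return `samplingRate`: Hz; `annotations`: data.frame of start/end
#'   seconds; `nChannels`: integer; `ehgSignals`: channels x samples
#'   matrix (for preprocessed recordings, a list with `filtered` and
#'   `normalized` matrices); `tocoSignal`: numeric vector;
#'   `segmentInfo`: data.frame; `droppedWindows`: character vector.
#' @name ehg-accessors
#' @aliases samplingRate annotations nChannels ehgSignals tocoSignal
#'   segmentInfo droppedWindows
NULL

#' @rdname ehg-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname ehg-accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))

#' @rdname ehg-accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname ehg-accessors
#' @export
setGeneric("ehgSignals", function(object) standardGeneric("ehgSignals"))

#' @rdname ehg-accessors
#' @export
setGeneric("tocoSignal", function(object) standardGeneric("tocoSignal"))

#' @rdname ehg-accessors
#' @export
setGeneric("segmentInfo", function(object) standardGeneric("segmentInfo"))

#' @rdname ehg-accessors
#' @export
setGeneric("droppedWindows", function(object) standardGeneric("droppedWindows"))

#' @rdname ehg-accessors
setMethod("samplingRate", "EHGRecording", function(object) object@samplingRate)
#' @rdname ehg-accessors
setMethod("samplingRate", "PreprocessedRecording",
          function(object) object@samplingRate)
#' @rdname ehg-accessors
setMethod("samplingRate", "SegmentSet", function(object) object@samplingRate)

#' @rdname ehg-accessors
setMethod("annotations", "EHGRecording", function(object) object@annotations)
#' @rdname ehg-accessors
setMethod("annotations", "PreprocessedRecording",
          function(object) object@annotations)

#' @rdname ehg-accessors
setMethod("nChannels", "EHGRecording", function(object) nrow(object@ehg))
#' @rdname ehg-accessors
setMethod("nChannels", "PreprocessedRecording",
          function(object) nrow(object@filtered))

#' @rdname ehg-accessors
setMethod("ehgSignals", "EHGRecording", function(object) object@ehg)
#' @rdname ehg-accessors
setMethod("ehgSignals", "PreprocessedRecording", function(object)
  list(filtered = object@filtered, normalized = object@normalized))

#' @rdname ehg-accessors
setMethod("tocoSignal", "EHGRecording", function(object) object@toco)
#' @rdname ehg-accessors
setMethod("tocoSignal", "PreprocessedRecording", function(object) object@toco)

#' @rdname ehg-accessors
setMethod("segmentInfo", "SegmentSet", function(object) object@info)

#' @rdname ehg-accessors
setMethod("droppedWindows", "SegmentSet", function(object) object@dropped)

#' @describeIn SegmentSet-class number of segments.
#' @param x a `SegmentSet`.
#' @export
setMethod("length", "SegmentSet", function(x) nrow(x@info))

#' Retrieve the sample vectors of one segment
#'
#' @param object a [SegmentSet-class].
#' @param i segment index (row of [segmentInfo()]).
#' @return list with `unnormalized` and `normalized` numeric vectors.
#' @export
setGeneric("segmentSamples", function(object, i)
  standardGeneric("segmentSamples"))

#' @rdname segmentSamples
setMethod("segmentSamples", "SegmentSet", function(object, i) {
  stopifnot(i >= 1, i <= nrow(object@info))
  list(unnormalized = object@unnormalized[[i]],
       normalized = object@normalized[[i]])
})

setMethod("show", "RecordingConfig", function(object) {
  cat("RecordingConfig:", object@nChannels, "channels @",
      object@samplingRate, "Hz,", object@duration, "s,",
      object@nContractions, "contractions\n")
  cat("  power gain:", object@contractionPowerGain,
      " regularity:", object@contractionRegularity,
      " best channel:", object@bestChannel,
      "(boost", paste0(object@bestChannelBoost, ")"), "\n")
  cat("  artifacts: drift", object@baselineDriftAmplitude,
      "| 50 Hz", object@powerlineAmplitude,
      "| mECG", object@mecgAmplitude, "@", object@mecgRate, "Hz\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "EHGRecording", function(object) {
  cat("EHGRecording:", nrow(object@ehg), "channels x",
      ncol(object@ehg), "samples @", object@samplingRate, "Hz (",
      round(ncol(object@ehg) / object@samplingRate, 1), "s )\n")
  cat(" ", nrow(object@annotations), "annotated contractions\n")
})

setMethod("show", "PreprocessedRecording", function(object) {
  cat("PreprocessedRecording:", nrow(object@filtered), "channels x",
      ncol(object@filtered), "samples @", object@samplingRate, "Hz\n")
  cat("  low-pass", object@filterSpec@cutoff, "Hz (order",
      object@filterSpec@order, "), median kernel",
      object@filterSpec@medianKernel, "s\n")
})

setMethod("show", "SegmentSet", function(object) {
  tab <- table(object@info$label)
  cat("SegmentSet:", nrow(object@info), "segments (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  if (length(object@dropped))
    cat(" ", length(object@dropped), "windows dropped (see droppedWindows())\n")
})
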