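#' Extract labelled contraction / non-contraction segments
#'
#' For every annotated contraction `[s, e]`, cuts one contraction
#' segment over `[s, e]` and one non-contraction segment over
#' `[e + gap, e + gap + ncDuration]` from every channel of both the
#' filtered (un-normalized) and normalized signal variants. Time is
#' converted to the half-open sample interval
#' `[round(start * fs), round(end * fs))`.
#'
#' A non-contraction window that would run past the end of the
#' recording or intersect another annotated contraction is dropped
#' together with its paired contraction segment (on all channels), so
#' the two classes stay balanced; every drop is logged and available
#' via [droppedWindows()].
#'
#' @param pre a [PreprocessedRecording-class].
#' @param gap seconds between a contraction's end and the start of its
#'   paired non-contraction window (default 10).
#' @param ncDuration non-contraction window length in seconds
#'   (default 60).
#' @return a [SegmentSet-class]; empty (with a warning) if the
#'   recording has no annotations.
#' @examples
#' rec <- generateRecording(recordingConfig(duration = 500,
#'                                          nContractions = 2,
#'                                          nChannels = 2, seed = 11))
#' segs <- extractSegments(preprocessRecording(rec))
#' table(segmentInfo(segs)$label)
#' @export
extractSegments <- function(pre, gap = 10, ncDuration = 60) {
  stopifnot(is(pre, "PreprocessedRecording"), gap >= 0, ncDuration > 0)
  ann <- annotations(pre)
  fs <- samplingRate(pre)
  sig <- ehgSignals(pre)
  nSamples <- ncol(sig$filtered)
  totalDur <- nSamples / fs

  emptySet <- new("SegmentSet",
                  info = data.frame(segment_id = character(),
                                    channel = integer(),
                                    label = character(),
                                    start = numeric(), end = numeric()),
                  unnormalized = list(), normalized = list(),
                  samplingRate = fs, dropped = character())
  if (!nrow(ann)) {
    warning("recording has no contraction annotations; returning an empty set")
    return(emptySet)
  }
  if (is.unsorted(ann$start)) stop("annotations must be sorted")

  dropped <- character()
  keep <- data.frame(cStart = numeric(), cEnd = numeric(),
                     nStart = numeric(), nEnd = numeric())
  for (k in seq_len(nrow(ann))) {
    ns <- ann$end[k] + gap
    ne <- ns + ncDuration
    collides <- any(ns < ann$end & ne > ann$start)
    if (ne > totalDur + 1e-9) {
      dropped <- c(dropped, sprintf(
        "contraction %d [%.1f, %.1f]: non-contraction window [%.1f, %.1f] runs past the recording end (%.1f s); pair dropped",
        k, ann$start[k], ann$end[k], ns, ne, totalDur))
    } else if (collides) {
      dropped <- c(dropped, sprintf(
        "contraction %d [%.1f, %.1f]: non-contraction window [%.1f, %.1f] overlaps another contraction; pair dropped",
        k, ann$start[k], ann$end[k], ns, ne))
    } else {
      keep <- rbind(keep, data.frame(cStart = ann$start[k], cEnd = ann$end[k],
                                     nStart = ns, nEnd = ne))
    }
  }

  if (!nrow(keep)) {
    warning("all windows dropped; returning an empty set")
    out <- emptySet
    out@dropped <- dropped
    return(out)
  }

  slice <- function(mat, ch, s, e) {
    i0 <- round(s * fs) + 1
    i1 <- round(e * fs)
    mat[ch, i0:i1]
  }

  info <- list(); un <- list(); no <- list()
  idx <- 0
  for (ch in seq_len(nrow(sig$filtered))) {
    for (k in seq_len(nrow(keep))) {
      for (lab in c("contraction", "non_contraction")) {
        s <- if (lab == "contraction") keep$cStart[k] else keep$nStart[k]
        e <- if (lab == "contraction") keep$cEnd[k] else keep$nEnd[k]
        idx <- idx + 1
        info[[idx]] <- data.frame(
          segment_id = sprintf("ch%02d_%s_%03d", ch,
                               if (lab == "contraction") "c" else "nc", k),
          channel = ch, label = lab, start = s, end = e)
        un[[idx]] <- slice(sig$filtered, ch, s, e)
        no[[idx]] <- slice(sig$normalized, ch, s, e)
      }
    }
  }

  new("SegmentSet",
      info = do.call(rbind, info),
      unnormalized = un, normalized = no,
      samplingRate = fs, dropped = dropped)
}
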