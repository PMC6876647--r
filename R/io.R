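#' Write a recording to disk
#'
#' Column-oriented CSV layout: `<prefix>_signals.csv` holds one time
#' column (seconds) followed by `ehg1..ehgK` and `toco` columns;
#' `<prefix>_annotations.csv` holds `start_s,end_s`; the generating
#' configuration is echoed to `<prefix>_config.yaml`. UTF-8, '.'
#' decimal point, comma separator, header row.
#'
#' @param recording an [EHGRecording-class].
#' @param prefix file path prefix (directories are created).
#' @return (invisibly) the prefix.
#' @export
writeRecording <- function(recording, prefix) {
  stopifnot(is(recording, "EHGRecording"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  ehg <- ehgSignals(recording)
  fs <- samplingRate(recording)
  sig <- data.frame(time_s = (seq_len(ncol(ehg)) - 1) / fs)
  for (ch in seq_len(nrow(ehg))) sig[[paste0("ehg", ch)]] <- ehg[ch, ]
  sig$toco <- tocoSignal(recording)
  utils::write.csv(sig, paste0(prefix, "_signals.csv"), row.names = FALSE)
  ann <- annotations(recording)
  utils::write.csv(data.frame(start_s = ann$start, end_s = ann$end),
                   paste0(prefix, "_annotations.csv"), row.names = FALSE)
  cfg <- recording@config
  yaml::write_yaml(list(
    samplingRate = cfg@samplingRate, nChannels = cfg@nChannels,
    duration = cfg@duration, nContractions = cfg@nContractions,
    contractionDurationRange = cfg@contractionDurationRange,
    interContractionGapRange = cfg@interContractionGapRange,
    contractionPowerGain = cfg@contractionPowerGain,
    contractionRegularity = cfg@contractionRegularity,
    channelGainRange = cfg@channelGainRange,
    bestChannel = cfg@bestChannel,
    bestChannelBoost = cfg@bestChannelBoost,
    baselineModulation = cfg@baselineModulation,
    baselineDriftAmplitude = cfg@baselineDriftAmplitude,
    powerlineAmplitude = cfg@powerlineAmplitude,
    mecgAmplitude = cfg@mecgAmplitude, mecgRate = cfg@mecgRate,
    seed = cfg@seed), paste0(prefix, "_config.yaml"))
  invisible(prefix)
}

#' Read a recording written by [writeRecording()]
#'
#' Also accepts externally produced files in the same layout; when the
#' YAML config echo is absent, a configuration is reconstructed from
#' the signal file itself.
#'
#' @param prefix file path prefix used when writing.
#' @return an [EHGRecording-class].
#' @export
readRecording <- function(prefix) {
  sig <- utils::read.csv(paste0(prefix, "_signals.csv"))
  chCols <- grep("^ehg[0-9]+$", names(sig), value = TRUE)
  chCols <- chCols[order(as.integer(sub("ehg", "", chCols)))]
  if (!length(chCols)) stop("no ehg columns found")
  fs <- 1 / stats::median(diff(sig$time_s))
  fs <- round(fs, 6)
  ann <- utils::read.csv(paste0(prefix, "_annotations.csv"))
  cfgPath <- paste0(prefix, "_config.yaml")
  if (file.exists(cfgPath)) {
    y <- yaml::read_yaml(cfgPath)
    config <- recordingConfig(
      samplingRate = y$samplingRate, nChannels = y$nChannels,
      duration = y$duration, nContractions = y$nContractions,
      contractionDurationRange = unlist(y$contractionDurationRange),
      interContractionGapRange = unlist(y$interContractionGapRange),
      contractionPowerGain = y$contractionPowerGain,
      contractionRegularity = y$contractionRegularity,
      channelGainRange = unlist(y$channelGainRange),
      bestChannel = y$bestChannel, bestChannelBoost = y$bestChannelBoost,
      baselineModulation = y$baselineModulation,
      baselineDriftAmplitude = y$baselineDriftAmplitude,
      powerlineAmplitude = y$powerlineAmplitude,
      mecgAmplitude = y$mecgAmplitude, mecgRate = y$mecgRate,
      seed = y$seed)
  } else {
    config <- recordingConfig(
      samplingRate = fs, nChannels = length(chCols),
      duration = nrow(sig) / fs, nContractions = nrow(ann))
  }
  toco <- if ("toco" %in% names(sig)) pmax(sig$toco, 0) else
    numeric(nrow(sig))
  ehg <- t(as.matrix(sig[, chCols, drop = FALSE]))
  dimnames(ehg) <- NULL
  new("EHGRecording",
      ehg = ehg, toco = toco, samplingRate = fs,
      annotations = data.frame(start = as.numeric(ann$start_s),
                               end = as.numeric(ann$end_s)),
      config = config)
}

#' Write the segments of a segment set to disk
#'
#' Long-format segment store: `<prefix>_segments.csv` holds the info
#' table (segment_id, channel, label, start_s, end_s) and
#' `<prefix>_samples.csv` one row per sample (segment_id, sample index,
#' un-normalized and normalized value). Mind the size: a full 8-channel
#' session produces millions of sample rows, so this writer is opt-in
#' rather than part of [runPipeline()] output.
#'
#' @param segments a [SegmentSet-class].
#' @param prefix file path prefix.
#' @return (invisibly) the prefix.
#' @export
writeSegments <- function(segments, prefix) {
  stopifnot(is(segments, "SegmentSet"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  info <- segmentInfo(segments)
  utils::write.csv(data.frame(segment_id = info$segment_id,
                              channel = info$channel, label = info$label,
                              start_s = info$start, end_s = info$end),
                   paste0(prefix, "_segments.csv"), row.names = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nrow(info)), function(i) {
    ss <- segmentSamples(segments, i)
    data.frame(segment_id = info$segment_id[i],
               sample = seq_along(ss$unnormalized),
               unnormalized = ss$unnormalized,
               normalized = ss$normalized)
  }))
  utils::write.csv(samples, paste0(prefix, "_samples.csv"),
                   row.names = FALSE)
  invisible(prefix)
}
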