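#' End-to-end pipeline configuration
#'
#' Bundles the per-stage parameter objects with the segmentation
#' geometry, the outer fold count and one master seed. The master seed
#' overrides the recording seed and derives the per-channel
#' classification seeds, so a pipeline run is fully determined by its
#' configuration.
#'
#' @slot recording a [RecordingConfig-class].
#' @slot filter a [FilterSpec-class].
#' @slot gap seconds between contraction end and non-contraction start.
#' @slot ncDuration non-contraction window length (s).
#' @slot samEn a [SamEnParams-class].
#' @slot ly a [LyapunovParams-class].
#' @slot tree a [TreeParams-class].
#' @slot kFolds outer cross-validation folds.
#' @slot seed master seed.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(recording = "RecordingConfig", filter = "FilterSpec",
                 gap = "numeric", ncDuration = "numeric",
                 samEn = "SamEnParams", ly = "LyapunovParams",
                 tree = "TreeParams", kFolds = "numeric",
                 seed = "numeric"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@gap < 0) msg <- c(msg, "gap must be >= 0")
  if (object@ncDuration <= 0) msg <- c(msg, "ncDuration must be > 0")
  if (object@kFolds < 2) msg <- c(msg, "kFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn runPipeline construct a pipeline configuration.
#' @param recording a [RecordingConfig-class].
#' @param filter a [FilterSpec-class].
#' @param gap seconds between a contraction's end and its paired
#'   non-contraction window.
#' @param ncDuration non-contraction window length in seconds.
#' @param samEn a [SamEnParams-class].
#' @param ly a [LyapunovParams-class].
#' @param tree a [TreeParams-class].
#' @param kFolds outer cross-validation folds.
#' @param seed master seed propagated to every stochastic stage.
#' @export
pipelineConfig <- function(recording = recordingConfig(),
                           filter = filterSpec(), gap = 10,
                           ncDuration = 60, samEn = samEnParams(),
                           ly = lyapunovParams(), tree = treeParams(),
                           kFolds = 10, seed = 1) {
  new("PipelineConfig", recording = recording, filter = filter,
      gap = gap, ncDuration = ncDuration, samEn = samEn, ly = ly,
      tree = tree, kFolds = kFolds, seed = seed)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: seed", object@seed, "|", object@kFolds,
      "outer folds | gap", object@gap, "s | non-contraction",
      object@ncDuration, "s\n")
  show(object@recording)
})

#' Run the full contraction-classification pipeline
#'
#' Orchestrates generate -> preprocess -> segment -> featurize ->
#' classify -> evaluate for one synthetic recording. The TOCO trace is
#' carried along as a human-readable reference only and never enters
#' classification. Identical configurations (including seed) give
#' identical outputs up to floating-point determinism of the platform.
#'
#' When `outdir` is given, the run directory is made self-describing:
#' recording CSVs, the segment info table, the full feature table,
#' per-channel JSON reports, a combined metrics CSV (channels x AUC,
#' sensitivity, specificity, PPV, NPV, accuracy), an importance CSV
#' (mean and SD per feature per channel), the dropped-window log and a
#' YAML echo of the configuration.
#'
#' @param config a [PipelineConfig-class] from `pipelineConfig()`.
#' @param outdir optional output directory (created if missing).
#' @return (invisibly) a list with `recording`, `segments`, `features`
#'   (the feature table), `channels` (per-channel [runChannel()] +
#'   [channelReport()] results), `metrics` (combined data.frame, one
#'   row per channel), `importance` (long data.frame of per-channel
#'   mean/SD importances) and `bestLevels`.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(recording = recordingConfig(
#'   duration = 1500, nContractions = 6, nChannels = 2, seed = 2),
#'   kFolds = 4, seed = 2)
#' res <- runPipeline(cfg)
#' res$metrics
#' }
#' @export
runPipeline <- function(config, outdir = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)

  recCfg <- config@recording
  recCfg@seed <- config@seed
  recording <- generateRecording(recCfg)
  pre <- preprocessRecording(recording, config@filter)
  segments <- extractSegments(pre, gap = config@gap,
                              ncDuration = config@ncDuration)
  if (!length(segments)) stop("segmentation stage produced no segments")
  features <- featureTable(segments, samEn = config@samEn, ly = config@ly)

  channels <- list()
  metrics <- NULL
  importance <- NULL
  bestLevels <- numeric(recCfg@nChannels)
  for (ch in seq_len(recCfg@nChannels)) {
    tab <- features[features$channel == ch, ]
    run <- runChannel(tab, k = config@kFolds,
                      seed = config@seed + 1000L * ch,
                      params = config@tree)
    rep <- channelReport(run)
    channels[[ch]] <- list(run = run, report = rep)
    bestLevels[ch] <- run$avgBestLevel
    metrics <- rbind(metrics, data.frame(
      channel = ch, t(rep$mean), avgBestLevel = run$avgBestLevel,
      kruskalH = rep$repeatability$statistic,
      kruskalP = rep$repeatability$p.value))
    importance <- rbind(importance,
                        cbind(channel = ch, run$ranking))
  }
  rownames(metrics) <- NULL

  result <- list(recording = recording, segments = segments,
                 features = features, channels = channels,
                 metrics = metrics, importance = importance,
                 bestLevels = bestLevels, config = config)

  if (!is.null(outdir)) writePipelineOutputs(result, outdir)
  invisible(result)
}

#' @noRd
writePipelineOutputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeRecording(result$recording, file.path(outdir, "recording"))
  utils::write.csv(segmentInfo(result$segments),
                   file.path(outdir, "segments.csv"), row.names = FALSE)
  utils::write.csv(result$features,
                   file.path(outdir, "features.csv"), row.names = FALSE)
  utils::write.csv(result$metrics,
                   file.path(outdir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(result$importance,
                   file.path(outdir, "importance.csv"), row.names = FALSE)
  for (ch in seq_along(result$channels)) {
    x <- result$channels[[ch]]
    jsonlite::write_json(list(
      channel = ch,
      avgBestLevel = x$run$avgBestLevel,
      bestLevels = vapply(x$run$folds, `[[`, numeric(1), "bestLevel"),
      meanMetrics = as.list(x$report$mean),
      perFold = x$report$perFold,
      repeatability = x$report$repeatability,
      importance = x$run$ranking,
      top4 = x$run$ranking$feature[x$run$ranking$top4]),
      file.path(outdir, sprintf("channel%02d.json", ch)),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(x$run$oof,
                     file.path(outdir, sprintf("oof_channel%02d.csv", ch)),
                     row.names = FALSE)
  }
  log <- c(sprintf("seed: %s", result$config@seed),
           sprintf("R version: %s", R.version.string),
           sprintf("segments: %d (dropped windows: %d)",
                   length(result$segments),
                   length(droppedWindows(result$segments))),
           droppedWindows(result$segments))
  writeLines(log, file.path(outdir, "run.log"))
  invisible(outdir)
}

#' Standard simulation study conditions
#'
#' The four seeded session configurations used throughout the package's
#' validation studies (tests, acceptance script and vignette):
#' \describe{
#'   \item{planted}{the default conditions: 8 channels, 14 contractions
#'     in a 3400 s session, in-band power gain 2 and burst regularity
#'     0.8 -- difficulty calibrated to clinically reported
#'     contraction-classification performance. Used for importance
#'     recovery.}
#'   \item{channel}{as `planted` but with a strongly boosted best
#'     channel (burst amplitude x 3 on channel 1) and 20 contractions
#'     (40 segments per channel): the plant and the problem size are
#'     set so the planted channel's advantage dominates the sampling
#'     noise of a per-channel AUC estimate. Used for channel-ranking
#'     recovery.}
#'   \item{strong}{4 channels, overwhelming class signal (power gain 8,
#'     regularity 0.9): the pipeline should approach ceiling
#'     performance.}
#'   \item{null}{4 channels, 10 contractions, no planted class signal
#'     (gain 1, regularity 0): out-of-fold AUC should hover near
#'     chance.}
#' }
#'
#' @param type one of `"planted"`, `"channel"`, `"strong"`, `"null"`.
#' @param seed master seed for the run.
#' @return a [PipelineConfig-class].
#' @export
sessionConfig <- function(type = c("planted", "channel", "strong", "null"),
                          seed = 1) {
  type <- match.arg(type)
  rec <- switch(type,
    planted = recordingConfig(duration = 3400, nContractions = 14,
                              seed = seed),
    channel = recordingConfig(duration = 4700, nContractions = 20,
                              bestChannelBoost = 3, seed = seed),
    strong = recordingConfig(duration = 3400, nContractions = 14,
                             nChannels = 4, contractionPowerGain = 8,
                             contractionRegularity = 0.9, seed = seed),
    null = recordingConfig(duration = 2500, nContractions = 10,
                           nChannels = 4, contractionPowerGain = 1,
                           contractionRegularity = 0, seed = seed))
  pipelineConfig(recording = rec, seed = seed)
}

#' Aggregate feature importance over channels
#'
#' Mean of the per-channel fold-averaged Gini importances, ranked; the
#' whole-study analogue of the per-channel ranking.
#'
#' @param result a [runPipeline()] result.
#' @return data.frame with feature, meanImportance and rank.
#' @export
overallImportance <- function(result) {
  agg <- stats::aggregate(meanImportance ~ feature,
                          data = result$importance, FUN = mean)
  agg <- agg[order(-agg$meanImportance), ]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}
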