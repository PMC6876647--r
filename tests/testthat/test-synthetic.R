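test_that("generation is deterministic and annotations match the config", {
  cfg <- recordingConfig(duration = 700, nContractions = 4, nChannels = 2,
                         seed = 42)
  rec1 <- generateRecording(cfg)
  rec2 <- generateRecording(cfg)

  expect_equal(nrow(annotations(rec1)), 4)
  expect_identical(ehgSignals(rec1), ehgSignals(rec2))
  expect_identical(tocoSignal(rec1), tocoSignal(rec2))
  expect_identical(annotations(rec1), annotations(rec2))

  ann <- annotations(rec1)
  expect_true(all(ann$end > ann$start))
  expect_true(all(ann$end - ann$start >= 30 & ann$end - ann$start <= 60))
  expect_true(all(ann$start[-1] >= ann$end[-4]))      # disjoint
  expect_true(all(tocoSignal(rec1) >= 0))
  expect_equal(ncol(ehgSignals(rec1)), round(700 * 250))
})

test_that("planted contractions raise in-band power on every channel", {
  cfg <- recordingConfig(duration = 900, nContractions = 3, nChannels = 4,
                         contractionPowerGain = 4, seed = 7)
  rec <- generateRecording(cfg)
  ann <- annotations(rec)
  fs <- samplingRate(rec)
  ehg <- ehgSignals(rec)
  for (ch in seq_len(nChannels(rec))) {
    inside <- mean(sapply(seq_len(nrow(ann)), function(k) {
      idx <- (round(ann$start[k] * fs) + 1):round(ann$end[k] * fs)
      oracleBandPower(ehg[ch, idx], fs, 0.1, 3)
    }))
    gaps <- rbind(c(0, ann$start[1]),
                  cbind(ann$end[-nrow(ann)], ann$start[-1]),
                  c(ann$end[nrow(ann)], ncol(ehg) / fs))
    outside <- mean(apply(gaps, 1, function(g) {
      idx <- (round(g[1] * fs) + 1):round(g[2] * fs)
      oracleBandPower(ehg[ch, idx], fs, 0.1, 3)
    }))
    expect_gt(inside, outside)
  }
})

test_that("infeasible schedules fail loudly", {
  cfg <- recordingConfig(duration = 200, nContractions = 5, seed = 1)
  expect_error(generateRecording(cfg), "infeasible")
})

test_that("artifact injection matches its contract", {
  fs <- 250
  clean <- sin(2 * pi * 0.3 * (0:(60 * fs - 1)) / fs)

  quiet <- recordingConfig(duration = 60, nContractions = 0,
                           baselineModulation = 0,
                           baselineDriftAmplitude = 0,
                           powerlineAmplitude = 0, mecgAmplitude = 0)
  expect_identical(addArtifacts(clean, quiet), clean)

  set.seed(1)
  mains <- recordingConfig(duration = 60, nContractions = 0,
                           baselineDriftAmplitude = 0,
                           powerlineAmplitude = 1, mecgAmplitude = 0)
  x <- addArtifacts(clean, mains)
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  k50 <- which.min(abs(freq - 50))
  expect_true(all(P[k50] > P[c(k50 - 2, k50 + 2)]))   # local maximum at 50 Hz

  set.seed(2)
  ecg <- recordingConfig(duration = 60, nContractions = 0,
                         baselineDriftAmplitude = 0,
                         powerlineAmplitude = 0, mecgAmplitude = 3,
                         mecgRate = 1.2)
  spikes <- addArtifacts(numeric(60 * fs), ecg)
  count <- oracleSpikeCount(spikes, 1.5)
  expect_true(abs(count - 72) <= 2)                   # ~ rate x duration
})

test_that("higher burst regularity lowers contraction sample entropy", {
  meanSamEn <- function(reg) {
    vals <- sapply(1:20, function(s) {
      cfg <- recordingConfig(duration = 420, nContractions = 2,
                             nChannels = 1, contractionRegularity = reg,
                             contractionPowerGain = 3, seed = 1000 + s)
      rec <- generateRecording(cfg)
      segs <- extractSegments(preprocessRecording(rec))
      info <- segmentInfo(segs)
      idx <- which(info$label == "contraction")
      mean(sapply(idx, function(i)
        suppressWarnings(sampleEntropy(segmentSamples(segs, i)$unnormalized))))
    })
    mean(vals)
  }
  s0 <- meanSamEn(0)
  s5 <- meanSamEn(0.5)
  s1 <- meanSamEn(1)
  expect_gt(s0, s1)
  expect_gte(s0 + 0.05, s5)   # middle point within noise of monotone order
  expect_gte(s5 + 0.05, s1)
})
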