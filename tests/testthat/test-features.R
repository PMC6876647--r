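test_that("time-domain characteristics match hand-computed examples", {
  const <- timeDomainFeatures(c(1, 1, 1, 1))
  expect_equal(unname(const[c("RMS", "MAV", "STD", "VAR", "SI", "DAS", "AAC")]),
               c(1, 1, 0, 0, 3, 0, 0))
  expect_equal(unname(const["LOG"]), 1, tolerance = 1e-9)

  alt <- timeDomainFeatures(c(1, -1, 1, -1))
  expect_equal(unname(alt[c("RMS", "MAV", "STD", "VAR", "SI", "DAS", "AAC")]),
               c(1, 1, 1, 1, 3, 2, 1.5))
  expect_equal(unname(alt["LOG"]), 1, tolerance = 1e-9)

  expect_error(timeDomainFeatures(5), "2 samples")
})

test_that("every direct-summation formula matches its naive oracle", {
  set.seed(10)
  for (rep in 1:50) {
    n <- sample(10:200, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    td <- timeDomainFeatures(x)
    expect_equal(unname(td["RMS"]), oracleRMS(x), tolerance = 1e-10)
    expect_equal(unname(td["STD"]), oracleSTD(x), tolerance = 1e-10)
    expect_equal(unname(td["LOG"]), oracleLOG(x), tolerance = 1e-10)
    expect_equal(unname(td["MAV"]), oracleMAV(x), tolerance = 1e-10)
    expect_equal(unname(td["SI"]), oracleSI(x), tolerance = 1e-10)
    expect_equal(unname(td["DAS"]), oracleDAS(x), tolerance = 1e-10)
    expect_equal(unname(td["AAC"]), oracleAAC(x), tolerance = 1e-10)
    expect_equal(unname(td["VAR"]), oracleVAR(x), tolerance = 1e-10)
    expect_equal(timeReversibility(x), oracleTR(x), tolerance = 1e-10)
    # internal consistency
    expect_equal(unname(td["VAR"]), unname(td["RMS"]^2) - mean(x)^2,
                 tolerance = 1e-10)
    expect_equal(unname(td["STD"]), sqrt(unname(td["VAR"])),
                 tolerance = 1e-12)
  }
})

test_that("characteristics scale with their stated homogeneity degrees", {
  set.seed(11)
  x <- rnorm(100)
  base <- timeDomainFeatures(x)
  for (c in c(0.5, 2, 10)) {
    sc <- timeDomainFeatures(c * x)
    expect_equal(unname(sc[c("RMS", "STD", "MAV", "DAS", "AAC")]),
                 c * unname(base[c("RMS", "STD", "MAV", "DAS", "AAC")]),
                 tolerance = 1e-10)
    expect_equal(unname(sc["LOG"]), c * unname(base["LOG"]),
                 tolerance = 1e-6)
    expect_equal(unname(sc[c("SI", "VAR")]),
                 c^2 * unname(base[c("SI", "VAR")]), tolerance = 1e-10)
    expect_equal(timeReversibility(c * x), c^3 * timeReversibility(x),
                 tolerance = 1e-10)
  }
})

test_that("spectral characteristics behave on known inputs", {
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  sp <- spectralFeatures(sin(2 * pi * 1 * t), fs)
  expect_equal(unname(sp["PF"]), 1, tolerance = 1e-9)   # exact bin
  expect_equal(unname(sp["MF"]), 1, tolerance = 1e-9)

  expect_equal(spectralFeatures(numeric(100), fs),
               c(PF = 0, MF = 0, Power = 0))

  # documented convention: Power equals the Hann^2-weighted mean square
  # over fs^2 (time-domain identity)
  set.seed(12)
  x <- rnorm(1000)
  w <- 0.5 * (1 - cos(2 * pi * (0:999) / 999))
  expect_equal(unname(spectralFeatures(x, fs)["Power"]),
               sum(x^2 * w^2) / sum(w^2) / fs^2, tolerance = 1e-10)

  # full agreement with an O(n^2) DFT oracle on short vectors
  for (rep in 1:5) {
    y <- rnorm(64)
    expect_equal(spectralFeatures(y, fs), oracleSpectral(y, fs),
                 tolerance = 1e-8)
  }
})

test_that("time reversibility is antisymmetric under time reversal", {
  expect_equal(timeReversibility(c(0, 1, 0, 1)), 1 / 3)
  expect_equal(timeReversibility(rep(2, 50)), 0)
  set.seed(13)
  for (rep in 1:10) {
    x <- rnorm(50)
    expect_equal(timeReversibility(rev(x)), -timeReversibility(x),
                 tolerance = 1e-12)
  }
  expect_error(timeReversibility(c(1, 2), tau = 2), "longer than")
})

test_that("sample entropy matches brute-force template counting exactly", {
  set.seed(14)
  cases <- expand.grid(m = 1:3, n = c(60, 120, 200))
  for (i in seq_len(nrow(cases))) {
    m <- cases$m[i]; n <- cases$n[i]
    x <- rnorm(n)
    p <- samEnParams(m = m, nTarget = NA)
    r <- 0.2 * sd(x)
    expect_identical(suppressWarnings(sampleEntropy(x, p)),
                     oracleSamEn(x, m, r))
  }
  # autocorrelation-based tolerance agrees with the oracle at its r
  x <- as.numeric(arima.sim(list(ar = 0.9), 150))
  p2 <- samEnParams(m = 2, nTarget = NA, rStrategy = "autocorr_zero_cross")
  ac <- acf(x, lag.max = length(x) - 2, plot = FALSE)$acf[-1]
  L <- which(ac <= 0)[1]
  r2 <- 0.2 * sd(x[(L + 1):length(x)] - x[seq_len(length(x) - L)])
  expect_identical(suppressWarnings(sampleEntropy(x, p2)),
                   oracleSamEn(x, 2, r2))
})

test_that("sample entropy conventions and invariances hold", {
  expect_equal(sampleEntropy(rep(1, 600)), 0)
  set.seed(15)
  x <- rnorm(700)
  expect_equal(suppressWarnings(sampleEntropy(3.7 * x)),
               suppressWarnings(sampleEntropy(x)))     # scale-invariant

  # regularity lowers entropy: white noise vs 1 Hz sinusoid at m = 8
  t <- seq(0, 60, length.out = 15000)
  vals <- sapply(1:20, function(s) {
    set.seed(400 + s)
    noise <- suppressWarnings(sampleEntropy(rnorm(15000)))
    tone <- suppressWarnings(
      sampleEntropy(sin(2 * pi * t + runif(1, 0, 2 * pi))))
    noise - tone
  })
  expect_gt(mean(vals), 0)
})

test_that("the Lyapunov estimator recovers known exponents", {
  x <- logisticMap(500)
  ly <- lyapunovLargest(x, lyapunovParams(resampleLength = NA))
  expect_lt(abs(ly - log(2)), 0.15)

  sines <- sapply(seq(0, 2, by = 0.5), function(ph) {
    t <- seq(0, 10, length.out = 500)
    lyapunovLargest(sin(2 * pi * t + ph), lyapunovParams(resampleLength = NA))
  })
  expect_lte(mean(sines), 0.05)

  expect_warning(v <- lyapunovLargest(rep(1, 500)), "constant")
  expect_equal(v, 0)
})

test_that("the feature vector has 24 named entries with correct provenance", {
  set.seed(16)
  un <- rnorm(2000, sd = 4)
  no <- un / max(abs(un))
  fv <- suppressWarnings(featureVector(un, no, fs = 250))
  expect_length(fv, 24)
  expect_identical(names(fv), featureNames())
  expect_false(anyNA(fv))

  # identical variants: suffixed features equal their originals
  fv2 <- suppressWarnings(featureVector(no, no, fs = 250))
  for (f in c("RMS", "LOG", "SI", "MAV", "DAS", "AAC", "STD", "VAR",
              "TR", "Power"))
    expect_equal(unname(fv2[paste0(f, "2")]), unname(fv2[f]))

  # scaling the un-normalized variant only: scale-invariant features
  # unchanged, amplitude features scale with their degree
  for (c in c(0.5, 2, 10)) {
    fvc <- suppressWarnings(featureVector(c * un, no, fs = 250))
    expect_equal(unname(fvc[c("MF", "PF", "SamEn")]),
                 unname(fv[c("MF", "PF", "SamEn")]))
    expect_equal(unname(fvc["RMS"]), c * unname(fv["RMS"]),
                 tolerance = 1e-10)
    expect_equal(unname(fvc["Power"]), c^2 * unname(fv["Power"]),
                 tolerance = 1e-10)
    expect_equal(unname(fvc[paste0(c("RMS", "Power"), "2")]),
                 unname(fv[paste0(c("RMS", "Power"), "2")]))
  }
})

test_that("featureTable returns one labelled row per segment", {
  rec <- generateRecording(recordingConfig(duration = 500,
                                           nContractions = 2,
                                           nChannels = 2, seed = 17))
  segs <- extractSegments(preprocessRecording(rec))
  ft <- suppressWarnings(featureTable(segs))
  expect_equal(nrow(ft), length(segs))
  expect_true(all(featureNames() %in% names(ft)))
  expect_true(all(c("segment_id", "channel", "label") %in% names(ft)))
  expect_false(anyNA(ft[, featureNames()]))
  nonneg <- c("RMS", "STD", "MAV", "SI", "DAS", "AAC", "VAR", "Power")
  expect_true(all(ft[, nonneg] >= 0))
  expect_true(all(ft$MF >= 0 & ft$MF <= 125 & ft$PF >= 0 & ft$PF <= 125))
})
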