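# Independent oracle implementations used to cross-check the package:
# naive direct-summation formulas with explicit loops, brute-force
# template counting, O(n^2) DFT and pairwise AUC. Deliberately slow and
# written without reference to the package internals.

oracleRMS <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2
  sqrt(s / length(x))
}

oracleMean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracleSTD <- function(x) {
  mu <- oracleMean(x)
  s <- 0
  for (v in x) s <- s + (v - mu)^2
  sqrt(s / length(x))
}

oracleVAR <- function(x) oracleSTD(x)^2

oracleLOG <- function(x) {
  s <- 0
  for (v in x) s <- s + log(abs(v) + 1e-12)
  exp(s / length(x))
}

oracleMAV <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracleSI <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + x[i]^2
  s
}

oracleDAS <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + (x[i + 1] - x[i])^2
  sqrt(s / (n - 1))
}

oracleAAC <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + abs(x[i + 1] - x[i])
  s / n
}

oracleTR <- function(x, tau = 1) {
  n <- length(x)
  s <- 0
  for (i in (tau + 1):n) s <- s + (x[i] - x[i - tau])^3
  s / (n - tau)
}

# O(n^2) DFT; spectral quantities under the package's documented
# convention (one-sided Hann periodogram PSD), computed from scratch.
oracleSpectral <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  xw <- x * w
  nb <- floor(n / 2) + 1
  P <- numeric(nb)
  for (k in seq_len(nb)) {
    re <- 0; im <- 0
    for (j in seq_len(n)) {
      ang <- -2 * pi * (k - 1) * (j - 1) / n
      re <- re + xw[j] * cos(ang)
      im <- im + xw[j] * sin(ang)
    }
    P[k] <- (re^2 + im^2) * (if (k == 1 || (n %% 2 == 0 && k == nb)) 1 else 2)
  }
  P <- P / (fs * sum(w^2))
  freq <- (seq_len(nb) - 1) * fs / n
  cum <- cumsum(P)
  c(PF = freq[which.max(P)],
    MF = freq[which(cum >= cum[nb] / 2)[1]],
    Power = sum(P) / n / fs)
}

# Brute-force sample entropy: double loop over template pairs,
# Chebyshev distance, self-matches excluded, templates 1..N-m for both
# lengths.
oracleSamEn <- function(x, m, r) {
  n <- length(x) - m
  A <- 0; B <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(-log(2 / (n * (n - 1))))
  -log(A / B)
}

# Pairwise-comparison AUC (Mann-Whitney with ties counted 1/2).
oracleAUC <- function(labels, scores) {
  pos <- scores[labels == "contraction"]
  neg <- scores[labels == "non_contraction"]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# In-band power via the raw (rectangular) periodogram, independent of
# the package's Hann convention.
oracleBandPower <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq >= lo & freq <= hi
  sum(X[keep]) / n  # mean-square contribution of the band (one side)
}

# Rising-edge threshold detector used for spike counting.
oracleSpikeCount <- function(x, thr) {
  above <- x > thr
  sum(diff(above) == 1) + as.integer(above[1])
}

# Small fake preprocessed recording with exactly controlled annotations;
# sample values encode (channel, index) so slices are verifiable.
fakePre <- function(ann, duration, fs = 10, nch = 2) {
  n <- round(duration * fs)
  filtered <- t(sapply(seq_len(nch), function(ch) ch * 1e6 + seq_len(n)))
  normalized <- filtered / max(abs(filtered))
  new("PreprocessedRecording",
      filtered = filtered, normalized = normalized,
      toco = numeric(n), samplingRate = fs,
      annotations = ann, filterSpec = filterSpec())
}

logisticMap <- function(n = 500, x0 = 0.2) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}
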