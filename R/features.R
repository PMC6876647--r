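#' Fixed order of the 24 waveform characteristics
#'
#' The first 14 are computed on the un-normalized segment (RMS through
#' SamEn); the remaining 10 (suffix `2`) are recomputed on the
#' normalized segment. MF, PF, SamEn and Ly are computed only once
#' because they are unchanged by (or undefined under) per-channel
#' amplitude scaling.
#'
#' @return character vector of the 24 feature names in canonical
#'   column order.
#' @export
featureNames <- function() {
  c("RMS", "STD", "LOG", "MAV", "SI", "DAS", "AAC", "VAR",
    "MF", "PF", "Power", "TR", "Ly", "SamEn",
    "RMS2", "LOG2", "SI2", "MAV2", "DAS2", "AAC2", "STD2", "VAR2",
    "TR2", "Power2")
}

#' Resample a segment to a fixed length by linear interpolation
#' @noRd
resampleTo <- function(x, nTarget) {
  if (is.na(nTarget) || length(x) == nTarget) return(x)
  stats::approx(seq_along(x), x, n = nTarget)$y
}

#' Time-domain waveform characteristics
#'
#' Direct-summation amplitude statistics of one segment:
#' \describe{
#'   \item{RMS}{\eqn{\sqrt{\sum x_i^2 / N}}}
#'   \item{STD}{population standard deviation
#'     \eqn{\sqrt{\sum (x_i - \mu)^2 / N}}}
#'   \item{LOG}{log detector \eqn{\exp(\frac{1}{N}\sum \log(|x_i| + \epsilon))},
#'     \eqn{\epsilon = 10^{-12}} guarding zeros}
#'   \item{MAV}{mean absolute value \eqn{\sum |x_i| / N}}
#'   \item{SI}{simple square integral \eqn{\sum_{i=1}^{N-1} x_i^2}
#'     (upper limit N-1: the last sample is excluded)}
#'   \item{DAS}{difference absolute standard deviation
#'     \eqn{\sqrt{\sum (x_{i+1}-x_i)^2 / (N-1)}}}
#'   \item{AAC}{average amplitude change \eqn{\sum |x_{i+1}-x_i| / N}}
#'   \item{VAR}{population variance \eqn{\sum (x_i - \mu)^2 / N}}
#' }
#'
#' @param x numeric sample vector, length >= 2, finite.
#' @return named numeric vector of the 8 statistics.
#' @examples
#' timeDomainFeatures(c(1, -1, 1, -1))
#' @export
timeDomainFeatures <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("non-finite samples")
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  d <- diff(x)
  c(RMS = sqrt(sum(x^2) / n),
    STD = sqrt(v),
    LOG = exp(sum(log(abs(x) + 1e-12)) / n),
    MAV = sum(abs(x)) / n,
    SI = sum(x[seq_len(n - 1)]^2),
    DAS = sqrt(sum(d^2) / (n - 1)),
    AAC = sum(abs(d)) / n,
    VAR = v)
}

#' One-sided Hann-tapered periodogram
#'
#' Power spectral density estimate used by [spectralFeatures()]:
#' length-N FFT of the Hann-windowed segment (DC bin included, no
#' demeaning), one-sided with doubling of interior bins, normalized by
#' `fs * sum(w^2)` so that `sum(P) * fs / N` equals the Hann^2-weighted
#' mean square of the signal.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @return list with `freq` (Hz) and `power` (PSD) vectors of length
#'   `floor(N/2) + 1`.
#' @export
periodogramPSD <- function(x, fs) {
  n <- length(x)
  w <- hannEnvelope(n)
  X <- stats::fft(x * w)
  nb <- floor(n / 2) + 1
  P <- Mod(X[seq_len(nb)])^2
  scale <- rep(2, nb)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nb] <- 1
  P <- P * scale / (fs * sum(w^2))
  list(freq = (seq_len(nb) - 1) * fs / n, power = P)
}

#' Spectral waveform characteristics
#'
#' Peak frequency (PF), median frequency (MF) and total Power of a
#' segment, from the one-sided Hann periodogram P(i) (see
#' [periodogramPSD()]):
#' PF is the frequency of the maximum of P (ties broken towards the
#' lowest frequency); MF is the first frequency at which the cumulative
#' power reaches half the total; Power is `sum(P) / N / fs`.
#' An all-zero segment returns (0, 0, 0) by convention.
#'
#' @param x numeric sample vector, length >= 8.
#' @param fs sampling rate in Hz.
#' @return named numeric vector `c(PF, MF, Power)`; PF and MF in Hz.
#' @examples
#' fs <- 250
#' t <- seq(0, 60 - 1 / fs, by = 1 / fs)
#' spectralFeatures(sin(2 * pi * 1 * t), fs)[c("PF", "MF")]
#' @export
spectralFeatures <- function(x, fs) {
  if (length(x) < 8) stop("need at least 8 samples")
  if (all(x == 0)) return(c(PF = 0, MF = 0, Power = 0))
  pg <- periodogramPSD(x, fs)
  P <- pg$power
  pf <- pg$freq[which.max(P)]
  cum <- cumsum(P)
  mf <- pg$freq[which(cum >= cum[length(cum)] / 2)[1]]
  c(PF = pf, MF = mf, Power = sum(P) / length(x) / fs)
}

#' Time reversibility
#'
#' Third moment of lagged increments,
#' \eqn{TR = \frac{1}{N-\tau} \sum_{i=\tau+1}^{N} (x_i - x_{i-\tau})^3};
#' zero for time-symmetric (e.g. linear Gaussian) processes.
#'
#' @param x numeric sample vector.
#' @param tau lag in samples (default 1).
#' @return TR value.
#' @examples
#' timeReversibility(c(0, 1, 0, 1))  # 1/3
#' @export
timeReversibility <- function(x, tau = 1) {
  n <- length(x)
  if (n <= tau) stop("signal must be longer than the lag")
  d <- x[(tau + 1):n] - x[seq_len(n - tau)]
  sum(d^3) / (n - tau)
}

#' Sample entropy
#'
#' \eqn{SamEn(m, r, N) = -\ln(B^{m+1}_r / B^m_r)} with template counts
#' computed under the Chebyshev (maximum) distance, self-matches
#' excluded, both template lengths sharing the index range
#' `1 .. N - m`. The segment is first resampled to `params@nTarget`
#' samples (default 500) by linear interpolation so segments of
#' different durations are compared at a common length.
#'
#' The tolerance r follows `params@rStrategy`:
#' `"std_fraction"` (default) uses `rFraction * SD(x)`, which makes the
#' value invariant under amplitude scaling; `"autocorr_zero_cross"`
#' uses `rFraction * SD` of the lag-L increment sequence, where L is
#' the first zero-crossing lag of the autocorrelation.
#'
#' Conventions for degenerate cases: a constant segment returns 0
#' (every template matches every other); if no template pair matches at
#' length m, or none of the m-matches extends to m + 1, the value is
#' capped at `-log(2 / (n (n - 1)))` (the largest conditional
#' probability resolvable from n templates) with a warning.
#'
#' @param x numeric sample vector.
#' @param params a [SamEnParams-class].
#' @return sample entropy in nats.
#' @examples
#' set.seed(1)
#' sampleEntropy(rnorm(300), samEnParams(m = 2, nTarget = NA))
#' @export
sampleEntropy <- function(x, params = samEnParams()) {
  stopifnot(is(params, "SamEnParams"))
  validObject(params)
  x <- resampleTo(x, params@nTarget)
  m <- params@m
  if (length(x) < m + 2) stop("segment too short for template length m")
  if (stats::sd(x) == 0) return(0)

  r <- switch(params@rStrategy,
    std_fraction = params@rFraction * stats::sd(x),
    autocorr_zero_cross = {
      ac <- stats::acf(x, lag.max = length(x) - 2, plot = FALSE,
                       demean = TRUE)$acf[-1]
      L <- which(ac <= 0)[1]
      if (is.na(L)) L <- max(1, length(x) %/% 2)
      inc <- x[(L + 1):length(x)] - x[seq_len(length(x) - L)]
      params@rFraction * stats::sd(inc)
    })
  if (!is.finite(r) || r == 0) return(0)

  n <- length(x) - m            # templates 1..n for both lengths
  Y <- matrix(x[outer(seq_len(n), 0:(m - 1), "+")], nrow = n)
  dm <- stats::dist(Y, method = "maximum")     # Chebyshev template distance
  B <- 2 * sum(dm <= r)         # ordered pairs, self-matches excluded
  dm1 <- pmax(dm, stats::dist(x[(1 + m):(n + m)], method = "maximum"))
  A <- 2 * sum(dm1 <= r)
  if (B == 0 || A == 0) {
    warning("no matching template pairs; sample entropy capped")
    return(-log(2 / (n * (n - 1))))
  }
  -log(A / B)
}

#' Largest Lyapunov exponent (Rosenstein estimator)
#'
#' Delay-embeds the (resampled) segment, finds each point's nearest
#' neighbour outside a Theiler window, and tracks the mean log distance
#' between neighbour pairs over `k = 0 .. kMax` steps. The exponent is
#' the slope of that divergence curve over its initial linear region:
#' with `fitRange = NULL` the region is detected automatically as the
#' steps up to the first crossing of half the total log-divergence rise
#' (at least 4 steps), which tracks the exponential regime before the
#' curve saturates at the attractor size.
#'
#' @param x numeric sample vector.
#' @param params a [LyapunovParams-class].
#' @return largest Lyapunov exponent in nats per (resampled) sample;
#'   0 with a warning for a constant segment.
#' @examples
#' x <- numeric(500); x[1] <- 0.2
#' for (i in 2:500) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
#' lyapunovLargest(x, lyapunovParams(resampleLength = NA))  # ~ log(2)
#' @export
lyapunovLargest <- function(x, params = lyapunovParams()) {
  stopifnot(is(params, "LyapunovParams"))
  validObject(params)
  x <- resampleTo(x, params@resampleLength)
  if (stats::sd(x) == 0) {
    warning("constant segment: Lyapunov exponent undefined, returning 0")
    return(0)
  }
  m <- params@embeddingDim
  d <- params@delay
  M <- length(x) - (m - 1) * d
  if (M < params@theiler + 10)
    stop("segment too short for the requested embedding")
  Y <- matrix(x[outer(seq_len(M), (seq_len(m) - 1) * d, "+")], nrow = M)

  D <- as.matrix(stats::dist(Y))
  th <- params@theiler
  for (i in seq_len(M))                       # Theiler exclusion band
    D[i, max(1, i - th):min(M, i + th)] <- Inf
  nn <- max.col(-D, ties.method = "first")

  K <- min(params@kMax, M - 2)
  L <- rep(NA_real_, K + 1)
  for (k in 0:K) {
    i <- which(seq_len(M) + k <= M & nn + k <= M)
    if (!length(i)) break
    dk <- sqrt(rowSums((Y[i + k, , drop = FALSE] -
                        Y[nn[i] + k, , drop = FALSE])^2))
    dk <- dk[dk > 0]
    if (length(dk)) L[k + 1] <- mean(log(dk))
  }
  k <- (0:K)[!is.na(L)]
  L <- L[!is.na(L)]
  if (length(L) < 3) return(0)

  if (is.null(params@fitRange)) {
    rise <- max(L) - L[1]
    if (rise < 1e-8) return(0)
    kf <- which(L >= L[1] + 0.5 * rise)[1]
    sel <- seq_len(max(kf, 4))
  } else {
    sel <- which(k >= params@fitRange[1] & k <= params@fitRange[2])
    if (length(sel) < 2) stop("fitRange selects fewer than 2 points")
  }
  unname(stats::coef(stats::lm(L[sel] ~ k[sel]))[2])
}

#' The 24-characteristic feature vector of one segment pair
#'
#' Computes the full feature vector for one segment carried in both
#' signal variants: RMS, STD, LOG, MAV, SI, DAS, AAC, VAR, MF, PF,
#' Power, TR, Ly and SamEn from the un-normalized samples, and RMS2,
#' LOG2, SI2, MAV2, DAS2, AAC2, STD2, VAR2, TR2 and Power2 from the
#' normalized samples. MF, PF, SamEn (scale-invariant under the default
#' tolerance strategy) and Ly (normalization distorts it) are computed
#' once, on the un-normalized variant.
#'
#' @param unnormalized numeric sample vector (filtered variant).
#' @param normalized numeric sample vector (normalized variant), same
#'   length.
#' @param fs sampling rate in Hz.
#' @param samEn a [SamEnParams-class].
#' @param ly a [LyapunovParams-class].
#' @return named numeric vector of length 24 in [featureNames()] order.
#' @export
featureVector <- function(unnormalized, normalized, fs,
                          samEn = samEnParams(), ly = lyapunovParams()) {
  if (length(unnormalized) != length(normalized))
    stop("segment variants must have equal length")
  withName <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("feature ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  td <- withName("time-domain", timeDomainFeatures(unnormalized))
  sp <- withName("spectral", spectralFeatures(unnormalized, fs))
  tr <- withName("TR", timeReversibility(unnormalized))
  lyv <- withName("Ly", lyapunovLargest(unnormalized, ly))
  se <- withName("SamEn", sampleEntropy(unnormalized, samEn))
  td2 <- withName("time-domain (normalized)", timeDomainFeatures(normalized))
  sp2 <- withName("spectral (normalized)", spectralFeatures(normalized, fs))
  tr2 <- withName("TR2", timeReversibility(normalized))
  out <- c(td[c("RMS", "STD", "LOG", "MAV", "SI", "DAS", "AAC", "VAR")],
           MF = unname(sp["MF"]), PF = unname(sp["PF"]),
           Power = unname(sp["Power"]), TR = tr, Ly = lyv, SamEn = se,
           RMS2 = unname(td2["RMS"]), LOG2 = unname(td2["LOG"]),
           SI2 = unname(td2["SI"]), MAV2 = unname(td2["MAV"]),
           DAS2 = unname(td2["DAS"]), AAC2 = unname(td2["AAC"]),
           STD2 = unname(td2["STD"]), VAR2 = unname(td2["VAR"]),
           TR2 = tr2, Power2 = unname(sp2["Power"]))
  names(out) <- featureNames()
  stopifnot(!anyNA(out))
  out
}

#' Feature table for a whole segment set
#'
#' One row per segment: metadata columns (segment_id, channel, label,
#' start, end) followed by the 24 characteristics in [featureNames()]
#' order.
#'
#' @param segments a [SegmentSet-class].
#' @param samEn a [SamEnParams-class].
#' @param ly a [LyapunovParams-class].
#' @return data.frame with `nrow = length(segments)`.
#' @export
featureTable <- function(segments, samEn = samEnParams(),
                         ly = lyapunovParams()) {
  stopifnot(is(segments, "SegmentSet"))
  info <- segmentInfo(segments)
  fs <- samplingRate(segments)
  if (!nrow(info))
    return(cbind(info, as.data.frame(matrix(numeric(), 0, 24,
                 dimnames = list(NULL, featureNames())))))
  feats <- t(vapply(seq_len(nrow(info)), function(i) {
    ss <- segmentSamples(segments, i)
    featureVector(ss$unnormalized, ss$normalized, fs, samEn, ly)
  }, numeric(24)))
  cbind(info, as.data.frame(feats))
}
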