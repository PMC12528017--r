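## The eight windowed fatigue features. Time domain: RMS, IEMG (rectified
## sum), waveform length, slope-sign changes. Frequency domain: median
## frequency and root-mean-square frequency of a tapered periodogram.
## Nonlinear: sample entropy and Higuchi fractal dimension. Fatigue
## manifests as rising RMS/IEMG and falling MF/RMSF/SE/SSC.

FEATURE_NAMES <- c("RMS", "IEMG", "WL", "SSC", "MF", "RMSF", "SE", "FD")

#' Sliding-window start indices
#'
#' Windows start at sample 1, advance by the step and only complete
#' windows are kept: \code{floor((N - window) / step) + 1} windows.
#'
#' @param signal numeric vector.
#' @param cfg a \linkS4class{WindowConfig}.
#' @return list with \code{starts} (window start indices),
#'   \code{windowLen} and \code{step} (samples); empty starts with a
#'   warning when the signal is shorter than one window.
#' @export
slidingWindows <- function(signal, cfg) {
  w <- round(cfg@windowMs * cfg@fs / 1000)
  s <- round(cfg@stepMs * cfg@fs / 1000)
  n <- length(signal)
  if (n < w) {
    warning("signal shorter than one window; no windows produced")
    return(list(starts = integer(0), windowLen = w, step = s))
  }
  nWin <- (n - w) %/% s + 1L
  list(starts = seq(1L, by = s, length.out = nWin),
       windowLen = as.integer(w), step = as.integer(s))
}

#' Root mean square
#' @param x numeric vector.
#' @return \code{sqrt(mean(x^2))}.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Integrated EMG (rectified sum)
#'
#' Cumulative rectified amplitude \code{sum(|x|)}; rectification is
#' required for the value to measure activity on a zero-mean signal.
#'
#' @param x numeric vector.
#' @return nonnegative scalar.
#' @export
iemg <- function(x) sum(abs(x))

#' Waveform length
#' @param x numeric vector.
#' @return \code{sum(|diff(x)|)}.
#' @export
waveformLength <- function(x) sum(abs(diff(x)))

#' Slope sign changes
#'
#' Counts interior points where the first difference changes sign, with
#' both neighbouring differences exceeding the noise threshold
#' \code{delta} in magnitude.
#'
#' @param x numeric vector.
#' @param delta amplitude threshold (default 0: any strict sign change).
#' @return integer count.
#' @export
slopeSignChanges <- function(x, delta = 0) {
  d <- diff(x)
  if (length(d) < 2L) return(0L)
  d1 <- d[-length(d)]
  d2 <- d[-1]
  sum(d1 * d2 < 0 & abs(d1) > delta & abs(d2) > delta)
}

#' One-sided tapered periodogram
#'
#' Mean removal, Hann taper, then \code{|FFT|^2} over the nonnegative
#' frequency bins. Power is scaled so its sum is proportional to the
#' tapered signal power; only relative power matters for MF and RMSF.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return list with \code{freq} (Hz) and \code{power}.
#' @export
powerSpectrum <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  X <- fft(x * taper)
  half <- seq_len(n %/% 2 + 1L)
  list(freq = (half - 1) * fs / n, power = Mod(X[half])^2 / n)
}

#' Median frequency of a power spectrum
#'
#' The half-power crossing of the cumulative spectrum: the frequency at
#' which cumulative power reaches half of the total, refined by linear
#' interpolation inside the crossing bin so short windows are not
#' quantised to the bin grid. The result always lies within one bin of
#' the first bin whose cumulative power reaches half.
#'
#' @param freq frequencies in Hz.
#' @param power spectral power at \code{freq}.
#' @return frequency in Hz, or \code{NA} when total power is zero.
#' @export
medianFrequency <- function(freq, power) {
  tot <- sum(power)
  if (tot <= 0) return(NA_real_)
  cum <- cumsum(power)
  # relative slack so an exactly-half cumulative (e.g. two equal tones)
  # resolves to the lower crossing despite rounding
  i <- which(cum >= tot / 2 - 1e-9 * tot)[1]
  fHi <- freq[i]
  fLo <- if (i > 1) freq[i - 1] else 0
  cumLo <- if (i > 1) cum[i - 1] else 0
  fLo + (tot / 2 - cumLo) / power[i] * (fHi - fLo)
}

#' Mean (power-weighted average) frequency
#'
#' @inheritParams medianFrequency
#' @return \code{sum(freq * power) / sum(power)}, or NA for zero power.
#' @export
meanFrequency <- function(freq, power) {
  tot <- sum(power)
  if (tot <= 0) return(NA_real_)
  sum(freq * power) / tot
}

#' Root-mean-square frequency
#'
#' @inheritParams medianFrequency
#' @return \code{sqrt(sum(freq^2 * power) / sum(power))}, or NA for zero
#'   power.
#' @export
rmsFrequency <- function(freq, power) {
  tot <- sum(power)
  if (tot <= 0) return(NA_real_)
  sqrt(sum(freq^2 * power) / tot)
}

#' Sample entropy
#'
#' \code{-ln(A / B)} where B counts template pairs of length \code{m}
#' within Chebyshev tolerance \code{r = rFrac * sd(x)} and A counts the
#' same pairs extended to length m + 1 (self-matches excluded, pairs
#' counted once). Returns 0 when no length-m pairs match (a constant
#' signal matches everywhere and yields 0 through A = B); when B > 0 but
#' A = 0 the value is capped at \code{log} of the number of possible
#' pairs.
#'
#' @param x numeric vector, length >= 10 * m.
#' @param m template length (default 2).
#' @param rFrac tolerance as a fraction of \code{sd(x)} (default 0.2).
#' @return nonnegative scalar.
#' @export
sampleEntropy <- function(x, m = 2L, rFrac = 0.2) {
  N <- length(x)
  if (N < 10L * m) stop("window too short for sample entropy", call. = FALSE)
  r <- rFrac * sd(x)
  nt <- N - m  # templates usable at both lengths
  if (r == 0) {
    # degenerate tolerance: only exactly equal templates match
    r <- 0
  }
  # Chebyshev distance between templates i, j of length m (and m+1) via
  # running elementwise maxima of |x_i - x_j| lag matrices.
  dmax <- matrix(0, nt, nt)
  for (off in 0:(m - 1L)) {
    seg <- x[(1L + off):(nt + off)]
    dmax <- pmax(dmax, abs(outer(seg, seg, "-")))
  }
  Bm <- (sum(dmax <= r) - nt) / 2
  segp <- x[(1L + m):(nt + m)]
  dmaxp <- pmax(dmax, abs(outer(segp, segp, "-")))
  Am <- (sum(dmaxp <= r) - nt) / 2
  if (Bm == 0) return(0)
  if (Am == 0) return(log(nt * (nt - 1) / 2))
  -log(Am / Bm)
}

#' Higuchi fractal dimension
#'
#' Builds Higuchi's decimated sub-series at scales k = 1..kMax, averages
#' their normalised curve lengths L(k) and returns the slope of the
#' least-squares fit of log L(k) on log(1/k). Smooth curves give values
#' near 1, uncorrelated noise near 2.
#'
#' @param x numeric vector.
#' @param kMax largest scale (default 8); must be well below length(x)/2.
#' @return the fractal dimension estimate, or NA for a constant signal.
#' @export
higuchiFD <- function(x, kMax = 8L) {
  N <- length(x)
  Lk <- numeric(kMax)
  for (k in seq_len(kMax)) {
    Lm <- numeric(k)
    for (m0 in seq_len(k)) {
      idx <- seq(m0, N, by = k)
      ni <- length(idx) - 1L
      if (ni < 1L) return(NA_real_)
      Lm[m0] <- sum(abs(diff(x[idx]))) * (N - 1) / (ni * k) / k
    }
    Lk[k] <- mean(Lm)
  }
  if (any(Lk <= 0)) return(NA_real_)
  lx <- log(1 / seq_len(kMax))
  ly <- log(Lk)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Extract the eight windowed features from one channel
#'
#' Slides fixed windows over the signal and evaluates the features in the
#' canonical order RMS, IEMG, WL, SSC, MF, RMSF, SE, FD. Windows where a
#' spectral or nonlinear feature is undefined (e.g. zero power) yield NA
#' there, with the affected window count reported via a message.
#'
#' @param signal numeric vector (one filtered channel).
#' @param cfg a \linkS4class{WindowConfig}.
#' @param channel channel index recorded in the result.
#' @param features subset of \code{c("RMS","IEMG","WL","SSC","MF","RMSF",
#'   "SE","FD")} to compute (default all eight).
#' @param sscDelta threshold for \code{\link{slopeSignChanges}}.
#' @param seM,seRFrac sample-entropy parameters.
#' @param fdKMax Higuchi scale cap.
#' @return a \linkS4class{FeatureMatrix}.
#' @examples
#' trial <- generateTrial(simConfig(duration = 4))
#' fm <- extractFeatures(signalData(recording(trial))[, 1],
#'                       windowConfig(fs = 2000), features = c("RMS", "MF"))
#' fm
#' @export
extractFeatures <- function(signal, cfg, channel = 1L,
                            features = FEATURE_NAMES, sscDelta = 0,
                            seM = 2L, seRFrac = 0.2, fdKMax = 8L) {
  features <- match.arg(features, FEATURE_NAMES, several.ok = TRUE)
  sw <- slidingWindows(signal, cfg)
  nWin <- length(sw$starts)
  vals <- matrix(NA_real_, nWin, length(features),
                 dimnames = list(NULL, features))
  for (i in seq_len(nWin)) {
    xw <- signal[sw$starts[i]:(sw$starts[i] + sw$windowLen - 1L)]
    spec <- if (any(c("MF", "RMSF") %in% features))
      powerSpectrum(xw, cfg@fs) else NULL
    for (f in features) {
      vals[i, f] <- switch(f,
        RMS = rms(xw),
        IEMG = iemg(xw),
        WL = waveformLength(xw),
        SSC = slopeSignChanges(xw, sscDelta),
        MF = medianFrequency(spec$freq, spec$power),
        RMSF = rmsFrequency(spec$freq, spec$power),
        SE = if (sd(xw) == 0 && all(xw == xw[1]))
               0 else sampleEntropy(xw, seM, seRFrac),
        FD = higuchiFD(xw))
    }
  }
  nBad <- sum(!stats::complete.cases(vals))
  if (nBad > 0)
    message(sprintf("%d window(s) with undefined features flagged as NA",
                    nBad))
  centres <- (sw$starts - 1 + sw$windowLen / 2) / cfg@fs
  new("FeatureMatrix", values = vals,
      windowTimes = as.numeric(centres), channel = as.integer(channel))
}
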