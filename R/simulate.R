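## Synthetic sEMG generator. A trial is built as
##   x_c(t) = gain(u(t)) * [W h(t)]_c * carrier(mf(u(t)), t)
##            + noiseFloor * white_c(t)
## where h(t) are periodic synergy activation envelopes, W the planted
## mixing matrix, u(t) the monotone fatigue level, and the carrier a
## band-shaped stochastic process whose median frequency tracks mf(u).
## The carrier is shared across channels (a common interference-pattern
## approximation) so the noiseless rectified envelope matrix factorises
## exactly at rank nSynergies.

#' Periodic synergy activation envelopes
#'
#' Builds one nonnegative periodic envelope per synergy: a tonic baseline
#' plus a raised-cosine (Hann) burst per movement cycle, with bursts
#' phase-shifted evenly across synergies. Burst width is two cycle
#' fractions, so for k synergies the bursts overlap-add to a constant,
#' mimicking smoothly handed-over phases of a cyclic movement.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param fs sampling rate of the returned envelopes (default the signal
#'   rate in \code{config}).
#' @return matrix \code{nSynergies x n_samples} with values in [0, 1].
#' @examples
#' H <- activationEnvelopes(simConfig(duration = 3))
#' dim(H)
#' @export
activationEnvelopes <- function(config, fs = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (config@cycleRate <= 0 || config@duration <= 0)
    stop("cycleRate and duration must be positive", call. = FALSE)
  if (is.null(fs)) fs <- config@fs
  period <- 60 / config@cycleRate
  n <- round(config@duration * fs)
  t <- (seq_len(n) - 1) / fs
  k <- config@nSynergies
  a0 <- config@tonicLevel
  width <- 2 / max(k, 2L)  # burst width as fraction of the cycle
  H <- matrix(0, k, n)
  for (s in seq_len(k)) {
    phase <- ((t / period - (s - 1) / k) %% 1)
    burst <- ifelse(phase < width,
                    0.5 * (1 - cos(2 * pi * phase / width)), 0)
    H[s, ] <- a0 + (1 - a0) * burst
  }
  H
}

#' Band-shaped stochastic carrier with a target median frequency
#'
#' Shapes white Gaussian noise in the frequency domain with a symmetric
#' raised-cosine band mask centred on \code{mfTarget}, so the empirical
#' median frequency of the result tracks the target. Output is zero-mean,
#' unit-variance and bitwise reproducible for a given seed.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param mfTarget target median frequency, must lie in (0, fs/2).
#' @param seed RNG seed.
#' @param bandwidth flat-band width in Hz.
#' @param rolloff raised-cosine transition width in Hz.
#' @return numeric vector of length \code{n}.
#' @examples
#' x <- shapedNoiseCarrier(4000, 2000, 80, seed = 1)
#' sd(x)
#' @export
shapedNoiseCarrier <- function(n, fs, mfTarget, seed,
                               bandwidth = 40, rolloff = 10) {
  if (mfTarget <= 0 || mfTarget >= fs / 2)
    stop("mfTarget must lie in (0, fs/2)", call. = FALSE)
  half <- bandwidth / 2
  f1 <- max(mfTarget - half, 1)
  f2 <- min(mfTarget + half, fs / 2 - 1)
  # keep the mask symmetric about mfTarget even when clipped
  half <- min(mfTarget - f1, f2 - mfTarget)
  f1 <- mfTarget - half; f2 <- mfTarget + half
  white <- withSeed(seed, rnorm(n))
  X <- fft(white)
  fbin <- (seq_len(n) - 1) * fs / n
  fbin <- pmin(fbin, fs - fbin)  # two-sided frequency axis
  mask <- numeric(n)
  flat <- fbin >= f1 & fbin <= f2
  mask[flat] <- 1
  lo <- fbin < f1 & fbin > f1 - rolloff
  mask[lo] <- 0.5 * (1 + cos(pi * (f1 - fbin[lo]) / rolloff))
  hi <- fbin > f2 & fbin < f2 + rolloff
  mask[hi] <- 0.5 * (1 + cos(pi * (fbin[hi] - f2) / rolloff))
  y <- Re(fft(X * mask, inverse = TRUE)) / n
  y <- y - mean(y)
  y / sd(y)
}

## Time-varying carrier: overlap-add of Hann-windowed shaped-noise blocks
## whose target MF follows mf(t); amplitude renormalised by the summed
## squared window so the variance stays flat across block joins. A final
## slow automatic-gain stage divides out the stochastic amplitude
## envelope (below agcCutoff), so the short-time power of the carrier is
## essentially constant and planted amplitude trends are not buried in
## chi-square energy fluctuations.
timeVaryingCarrier <- function(n, fs, mfOfT, seed, blockSec = 0.5,
                               agcCutoff = 10, bandwidth = 40) {
  B <- round(blockSec * fs)
  hop <- B %/% 2L
  acc <- numeric(n + B)
  w2 <- numeric(n + B)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(B) - 1) / B))
  starts <- seq(1L, n, by = hop)
  for (b in seq_along(starts)) {
    i0 <- starts[b]
    centre <- min(i0 + B %/% 2L, n)
    mfb <- mfOfT[centre]
    blk <- shapedNoiseCarrier(B, fs, mfb, seed = deriveSeed(seed, 1000 + b),
                              bandwidth = bandwidth)
    idx <- i0:(i0 + B - 1L)
    acc[idx] <- acc[idx] + w * blk
    w2[idx] <- w2[idx] + w^2
  }
  out <- acc[seq_len(n)] / sqrt(pmax(w2[seq_len(n)], 1e-12))
  lf <- signal::butter(2, agcCutoff / (fs / 2), type = "low")
  env <- signal::filtfilt(lf, abs(out))
  env <- pmax(env, 0.1 * mean(env))
  out <- out / env
  (out - mean(out)) / sd(out)
}

#' Generate a simulated sEMG trial
#'
#' Produces a multi-channel recording with planted synergy structure,
#' rising amplitude and falling carrier median frequency as fatigue
#' progresses, together with the generative ground truth.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SimulatedTrial}.
#' @examples
#' trial <- generateTrial(simConfig(duration = 5))
#' trial
#' @export
generateTrial <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  fs <- config@fs
  n <- round(config@duration * fs)
  t <- (seq_len(n) - 1) / fs
  u <- pmin(1, pmax(0, config@fatigueProfile(t)))
  gain <- config@gainStart + (config@gainEnd - config@gainStart) * u
  mft <- config@mfStart + (config@mfEnd - config@mfStart) * u
  H <- activationEnvelopes(config)
  W <- config@mixingWeights
  if (!all(dim(W) == c(config@nChannels, config@nSynergies)))
    stop("mixingWeights shape mismatch with nChannels/nSynergies",
         call. = FALSE)
  modulation <- W %*% H                       # nChannels x n
  carrier <- timeVaryingCarrier(n, fs, mft, seed = config@seed)
  data <- t(modulation * rep(gain * carrier, each = nrow(modulation)))
  if (config@noiseFloor > 0) {
    noise <- withSeed(deriveSeed(config@seed, 7),
                      matrix(rnorm(n * config@nChannels), n,
                             config@nChannels))
    data <- data + config@noiseFloor * noise
  }
  rec <- rawRecording(data, fs)
  envFs <- 50
  keep <- seq(1L, n, by = max(1L, round(fs / envFs)))
  p <- config@labelFractions
  truth <- new("SimGroundTruth",
               fatigueLevel = u,
               trueH = H[, keep, drop = FALSE],
               trueW = W, envFs = fs / max(1L, round(fs / envFs)),
               labelBoundaries = list(
                 relaxed = c(0, p[1] * config@duration),
                 fatigued = c((1 - p[2]) * config@duration,
                              config@duration)))
  new("SimulatedTrial", recording = rec, groundTruth = truth,
      config = config)
}
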