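## Zero-phase filtering front end. All filters are applied forward and
## backward (filtfilt), which squares the magnitude response and cancels
## phase; corner attenuation therefore doubles in dB relative to the
## one-pass design. The first/last `edgeTrim` seconds carry filter
## transients and are meant to be excluded from windowing downstream.

applyByChannel <- function(rec, fun) {
  out <- apply(signalData(rec), 2, fun)
  rawRecording(out, samplingRate(rec), channelNames(rec))
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param cfg a \linkS4class{FilterConfig}; defaults to 20--150 Hz,
#'   order 4.
#' @return the filtered \linkS4class{RawRecording}.
#' @examples
#' rec <- recording(generateTrial(simConfig(duration = 2)))
#' filt <- bandpassFilter(rec)
#' @export
bandpassFilter <- function(rec, cfg = filterConfig()) {
  fs <- samplingRate(rec)
  if (cfg@bandHigh >= fs / 2)
    stop("bandHigh must be below the Nyquist frequency fs/2", call. = FALSE)
  if (cfg@bandLow <= 0) stop("bandLow must be positive", call. = FALSE)
  bf <- signal::butter(cfg@bandOrder,
                       c(cfg@bandLow, cfg@bandHigh) / (fs / 2),
                       type = "pass")
  applyByChannel(rec, function(x) signal::filtfilt(bf, x))
}

#' Zero-phase power-line notch filter
#'
#' Narrow band-stop centred on \code{notchFreq} with -3 dB width
#' \code{notchFreq / notchQ}. Warns (but still applies) when the notch
#' lies outside the band-pass range.
#'
#' @inheritParams bandpassFilter
#' @return the filtered \linkS4class{RawRecording}.
#' @export
notchFilter <- function(rec, cfg = filterConfig()) {
  fs <- samplingRate(rec)
  if (cfg@notchFreq < cfg@bandLow || cfg@notchFreq > cfg@bandHigh)
    warning("notch frequency lies outside the band-pass range")
  bw <- cfg@notchFreq / cfg@notchQ
  edges <- c(cfg@notchFreq - bw / 2, cfg@notchFreq + bw / 2) / (fs / 2)
  nf <- signal::butter(2, edges, type = "stop")
  applyByChannel(rec, function(x) signal::filtfilt(nf, x))
}

#' Rectified low-pass envelope
#'
#' Full-wave rectification followed by a zero-phase Butterworth low-pass
#' at \code{envelopeCutoff}, clipped at zero. This is the nonnegative
#' matrix handed to synergy analysis.
#'
#' @inheritParams bandpassFilter
#' @return nonnegative numeric matrix (samples x channels).
#' @export
rectifyEnvelope <- function(rec, cfg = filterConfig()) {
  fs <- samplingRate(rec)
  lf <- signal::butter(4, cfg@envelopeCutoff / (fs / 2), type = "low")
  env <- apply(abs(signalData(rec)), 2,
               function(x) signal::filtfilt(lf, x))
  env[env < 0] <- 0
  colnames(env) <- channelNames(rec)
  env
}

#' Drop filter-transient edges from a recording
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param trimSec seconds removed from each end (default 0.25).
#' @return the trimmed \linkS4class{RawRecording}.
#' @export
trimEdges <- function(rec, trimSec = 0.25) {
  n <- nrow(signalData(rec))
  k <- round(trimSec * samplingRate(rec))
  if (2 * k >= n) stop("recording shorter than twice the edge trim",
                       call. = FALSE)
  rawRecording(signalData(rec)[(k + 1):(n - k), , drop = FALSE],
               samplingRate(rec), channelNames(rec))
}

#' Band-pass then notch, the standard preprocessing chain
#'
#' @inheritParams bandpassFilter
#' @return the filtered \linkS4class{RawRecording}.
#' @export
preprocessRecording <- function(rec, cfg = filterConfig()) {
  notchFilter(bandpassFilter(rec, cfg), cfg)
}

#' Decimate an envelope matrix
#'
#' The 5 Hz-low-passed envelope is heavily oversampled at the raw rate;
#' synergy analysis uses a decimated copy. Plain subsampling is safe here
#' because the envelope is already band-limited far below the target rate.
#'
#' @param env envelope matrix (samples x channels) at rate \code{fs}.
#' @param fs rate of \code{env} in Hz.
#' @param targetFs decimated rate in Hz (default 50).
#' @return list with \code{env} (decimated matrix) and \code{fs}.
#' @export
decimateEnvelope <- function(env, fs, targetFs = 50) {
  by <- max(1L, round(fs / targetFs))
  list(env = env[seq(1L, nrow(env), by = by), , drop = FALSE],
       fs = fs / by)
}
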