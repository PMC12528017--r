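## Plain-text I/O: recordings and ground truth as CSV, configurations and
## reports as JSON.

#' Write a simulated trial to CSV + JSON files
#'
#' Writes \code{raw.csv} (\code{time,ch1..chN}), \code{truth.csv}
#' (\code{time,fatigue_level,label}; label is 0/1/NA by the configured
#' boundaries) and \code{config.json}.
#'
#' @param trial a \linkS4class{SimulatedTrial}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeTrialCSV <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- recording(trial)
  n <- nrow(signalData(rec))
  tt <- (seq_len(n) - 1) / samplingRate(rec)
  raw <- data.frame(time = tt, signalData(rec), check.names = FALSE)
  rawPath <- file.path(dir, "raw.csv")
  write.csv(raw, rawPath, row.names = FALSE)
  gt <- groundTruth(trial)
  lab <- assignLabels(tt, gt)
  truthPath <- file.path(dir, "truth.csv")
  write.csv(data.frame(time = tt, fatigue_level = gt@fatigueLevel,
                       label = lab),
            truthPath, row.names = FALSE)
  cfg <- simulationConfig(trial)
  cfgPath <- file.path(dir, "config.json")
  jsonlite::write_json(list(
    n_channels = cfg@nChannels, fs = cfg@fs, duration = cfg@duration,
    n_synergies = cfg@nSynergies, cycle_rate = cfg@cycleRate,
    mixing_weights = cfg@mixingWeights,
    dominant_channels = cfg@dominantChannels,
    tonic_level = cfg@tonicLevel,
    mf_start = cfg@mfStart, mf_end = cfg@mfEnd,
    gain_start = cfg@gainStart, gain_end = cfg@gainEnd,
    noise_floor = cfg@noiseFloor,
    label_fractions = cfg@labelFractions, seed = cfg@seed),
    cfgPath, auto_unbox = TRUE, digits = NA)
  invisible(c(raw = rawPath, truth = truthPath, config = cfgPath))
}

#' Write a synergy analysis result to plain-text files
#'
#' Writes \code{vaf_by_k.csv} (k, mean, max, min), \code{contributions.csv}
#' (channel, score) and \code{channels_selected.json}.
#'
#' @param res a \linkS4class{SynergyResult}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeSynergyResult <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vafPath <- file.path(dir, "vaf_by_k.csv")
  write.csv(vafByK(res), vafPath, row.names = FALSE)
  contribPath <- file.path(dir, "contributions.csv")
  write.csv(data.frame(channel = seq_along(contributions(res)),
                       score = contributions(res)),
            contribPath, row.names = FALSE)
  selPath <- file.path(dir, "channels_selected.json")
  jsonlite::write_json(list(k_selected = kSelected(res),
                            channels_selected = channelsSelected(res)),
                       selPath, auto_unbox = TRUE)
  invisible(c(vaf = vafPath, contributions = contribPath,
              selection = selPath))
}

#' Read a multi-channel recording from CSV
#'
#' Expects a header row and one column per channel; a \code{time} column,
#' if present, is dropped (the sampling rate is taken from \code{fs}).
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz.
#' @return a \linkS4class{RawRecording}.
#' @export
readRecordingCSV <- function(path, fs) {
  df <- read.csv(path, check.names = FALSE)
  if ("time" %in% names(df)) df$time <- NULL
  rawRecording(as.matrix(df), fs, names(df))
}
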