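test_that("activation envelopes are periodic, phase-shifted and bounded", {
  cfg <- simConfig(duration = 3, cycleRate = 40, seed = 1)
  H <- activationEnvelopes(cfg)
  expect_equal(dim(H), c(3L, 6000L))
  expect_true(all(H >= 0 & H <= 1 + 1e-12))
  # period 60/40 = 1.5 s = 3000 samples: values one period apart agree
  expect_lt(max(abs(H[, 1:3000] - H[, 3001:6000])), 1e-9)
  # exactly 2 complete bursts of the phase-0 synergy in 3 s
  peaks <- which(diff(sign(diff(H[1, ]))) == -2) + 1L
  expect_equal(sum(H[1, peaks] > 0.9), 2L)
  # other synergies are circularly shifted copies (by a third of a cycle)
  n <- ncol(H)
  for (s in 2:3) {
    shift <- (s - 1) * 1000L  # 3000-sample period / 3 synergies
    rotated <- H[1, ((seq_len(n) - 1 - shift) %% n) + 1L]
    expect_equal(H[s, ], rotated, tolerance = 1e-9)
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simConfig(duration = -1), "duration")
  expect_error(simConfig(mfStart = 60, mfEnd = 90), "mfEnd")
  expect_error(simConfig(gainStart = 2, gainEnd = 1), "gain")
  expect_error(simConfig(mixingWeights = matrix(1, 4, 3)), "mixingWeights")
})

test_that("shaped noise carrier hits its target median frequency", {
  x <- shapedNoiseCarrier(4000, 2000, 80, seed = 1)
  sp <- powerSpectrum(x, 2000)
  mf <- medianFrequency(sp$freq, sp$power)
  expect_gte(mf, 75); expect_lte(mf, 85)
  # determinism: identical seeds give bitwise-identical carriers
  expect_identical(x, shapedNoiseCarrier(4000, 2000, 80, seed = 1))
  # ordering: measured MF follows the target
  m60 <- local({
    y <- shapedNoiseCarrier(4000, 2000, 60, seed = 2)
    s <- powerSpectrum(y, 2000); medianFrequency(s$freq, s$power)
  })
  m90 <- local({
    y <- shapedNoiseCarrier(4000, 2000, 90, seed = 2)
    s <- powerSpectrum(y, 2000); medianFrequency(s$freq, s$power)
  })
  expect_lt(m60, m90)
  expect_error(shapedNoiseCarrier(1000, 2000, 1200, seed = 1), "fs/2")
})

test_that("generated trials are deterministic and respect the mixing", {
  cfg <- simConfig(duration = 4, seed = 7)
  t1 <- generateTrial(cfg)
  t2 <- generateTrial(cfg)
  expect_identical(signalData(recording(t1)), signalData(recording(t2)))
  expect_equal(nrow(signalData(recording(t1))), 8000L)
  gt <- groundTruth(t1)
  expect_true(all(diff(gt@fatigueLevel) >= 0))
  expect_true(all(gt@trueW >= 0) && all(gt@trueH >= 0))
  # an all-zero mixing row with zero noise floor gives a silent channel
  W <- defaultMixingWeights()
  W[8, ] <- 0
  tz <- generateTrial(simConfig(duration = 2, mixingWeights = W,
                                noiseFloor = 0, seed = 1))
  expect_equal(max(abs(signalData(recording(tz))[, 8])), 0)
})

test_that("planted fatigue signature appears in RMS and MF, and only then", {
  wcfg <- windowConfig(fs = 2000)
  firstLast <- function(v) {
    n <- length(v); k <- max(1, round(0.1 * n))
    c(mean(v[1:k], na.rm = TRUE), mean(v[(n - k + 1):n], na.rm = TRUE))
  }
  # control: no fatigue planted -> stationary RMS
  ctl <- generateTrial(simConfig(duration = 20, gainStart = 1, gainEnd = 1,
                                 mfStart = 80, mfEnd = 80, seed = 5))
  fmc <- extractFeatures(signalData(recording(ctl))[, 1], wcfg,
                         features = c("RMS"))
  fl <- firstLast(featureValues(fmc)[, "RMS"])
  expect_lt(abs(fl[2] - fl[1]) / fl[1], 0.10)
  # default: rising RMS, falling MF
  tr <- generateTrial(simConfig(duration = 20, seed = 5))
  fm <- extractFeatures(signalData(recording(tr))[, 1], wcfg,
                        features = c("RMS", "MF"))
  v <- featureValues(fm)
  flr <- firstLast(v[, "RMS"]); flm <- firstLast(v[, "MF"])
  expect_gt(flr[2], flr[1])
  expect_lt(flm[2], flm[1])
})

test_that("trial CSV round-trip preserves the signal", {
  tr <- generateTrial(simConfig(duration = 1, seed = 2))
  dir <- withr::local_tempdir()
  paths <- writeTrialCSV(tr, dir)
  expect_true(all(file.exists(paths)))
  rec <- readRecordingCSV(paths["raw"], fs = 2000)
  expect_equal(signalData(rec), signalData(recording(tr)),
               tolerance = 1e-6)
  truth <- read.csv(paths["truth"])
  expect_true(all(truth$label %in% c(0, 1, NA)))
})
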