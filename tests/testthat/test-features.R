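test_that("sliding windows cover only complete windows", {
  cfg <- windowConfig(windowMs = 100, stepMs = 25, fs = 2000)
  sw <- slidingWindows(numeric(1000), cfg)
  expect_equal(length(sw$starts), (1000 - 200) %/% 50 + 1)  # 17
  expect_equal(sw$starts[1], 1L)
  expect_warning(swShort <- slidingWindows(numeric(100), cfg), "shorter")
  expect_length(swShort$starts, 0L)
  # step = window tiles without overlap
  cfg2 <- windowConfig(windowMs = 100, stepMs = 100, fs = 2000)
  sw2 <- slidingWindows(numeric(1000), cfg2)
  expect_equal(diff(sw2$starts), rep(200L, 4))
})

test_that("time-domain features match closed forms", {
  expect_equal(rms(c(3, -3)), 3)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(numeric(8) * 0), 0)
  expect_equal(iemg(c(1, -2, 3)), 6)
  expect_equal(iemg(rep(0, 5)), 0)
  x <- c(0.3, -1.2, 2.2, 0.1)
  expect_equal(iemg(2 * x), 2 * iemg(x))
  expect_equal(waveformLength(c(1, 3, 2)), 3)
  expect_equal(waveformLength(rep(4, 9)), 0)
  expect_equal(waveformLength(seq(0, 1, length.out = 11)), 1)
  expect_equal(slopeSignChanges(1:10), 0L)
  expect_equal(slopeSignChanges(c(0, 1, 0, 1, 0)), 3L)
  expect_equal(slopeSignChanges(c(0, 1, 0, 1, 0), delta = 2), 0L)
})

test_that("periodogram localises tones and is flat for white noise", {
  fs <- 2000
  x <- sin(2 * pi * 80 * (0:1999) / fs)
  sp <- powerSpectrum(x, fs)
  expect_lte(abs(sp$freq[which.max(sp$power)] - 80), 1)
  flatness <- mean(vapply(1:10, function(s) {
    set.seed(s)
    p <- powerSpectrum(rnorm(1000), fs)$power[-1]
    exp(mean(log(p))) / mean(p)
  }, numeric(1)))
  expect_gte(flatness, 0.5)
  expect_equal(max(powerSpectrum(rep(0, 500), fs)$power), 0)
})

test_that("median, mean and RMS frequency follow their definitions", {
  fs <- 2000
  sp <- powerSpectrum(sin(2 * pi * 80 * (0:1999) / fs), fs)
  expect_lte(abs(medianFrequency(sp$freq, sp$power) - 80), 1)
  # uniform power -> midpoint of the axis (within a bin)
  f <- seq(0, 1000, by = 10)
  expect_lte(abs(medianFrequency(f, rep(1, length(f))) - 500), 10)
  # two equal tones: crossing sits at the lower tone (within a bin)
  x2 <- sin(2 * pi * 40 * (0:1999) / fs) + sin(2 * pi * 120 * (0:1999) / fs)
  sp2 <- powerSpectrum(x2, fs)
  mf2 <- medianFrequency(sp2$freq, sp2$power)
  expect_gte(mf2, 40 - 1); expect_lte(mf2, 41 + 1)
  expect_equal(meanFrequency(c(60, 80), c(1, 1)), 70)
  expect_lte(abs(rmsFrequency(sp$freq, sp$power) - 80), 1)
  expect_equal(rmsFrequency(c(60, 80), c(1, 1)), sqrt((60^2 + 80^2) / 2))
  expect_true(is.na(rmsFrequency(c(60, 80), c(0, 0))))
  expect_true(is.na(medianFrequency(c(60, 80), c(0, 0))))
})

test_that("sample entropy matches the brute-force oracle exactly", {
  expect_equal(sampleEntropy(rep(2.5, 50)), 0)
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(100)
    expect_identical(sampleEntropy(x), bruteSampEn(x))
  }
  # periodic signal is more regular than noise at equal length/variance
  n <- 200
  square <- rep(c(1, 1, 1, 1, -1, -1, -1, -1), length.out = n)
  for (s in 1:10) {
    set.seed(s)
    noise <- rnorm(n, sd = sd(square))
    expect_lt(sampleEntropy(square), sampleEntropy(noise))
  }
})

test_that("Higuchi dimension separates lines from noise", {
  line <- as.numeric(1:1000)
  fdLine <- higuchiFD(line)
  expect_gte(fdLine, 0.95); expect_lte(fdLine, 1.05)
  fdNoise <- vapply(1:10, function(s) {
    set.seed(s); higuchiFD(rnorm(1000))
  }, numeric(1))
  expect_gte(mean(fdNoise), 1.8); expect_lte(mean(fdNoise), 2.05)
  expect_true(all(fdLine < fdNoise))
})

test_that("extractFeatures fills the canonical matrix and flags NAs", {
  cfg <- windowConfig(fs = 2000)
  suppressMessages(fm <- extractFeatures(rep(0, 1000), cfg))
  v <- featureValues(fm)
  expect_equal(colnames(v),
               c("RMS", "IEMG", "WL", "SSC", "MF", "RMSF", "SE", "FD"))
  expect_true(all(v[, c("RMS", "IEMG", "WL", "SSC", "SE")] == 0))
  expect_true(all(is.na(v[, c("MF", "RMSF", "FD")])))
  # window centres advance by the step
  expect_equal(diff(windowTimes(fm))[1], 0.025)
})

test_that("amplitude scaling affects only the amplitude features", {
  set.seed(9)
  x <- shapedNoiseCarrier(2000, 2000, 80, seed = 9)
  cfg <- windowConfig(fs = 2000)
  a <- featureValues(extractFeatures(x, cfg))
  b <- featureValues(extractFeatures(3 * x, cfg))
  expect_equal(b[, "RMS"], 3 * a[, "RMS"], tolerance = 1e-9)
  expect_equal(b[, "IEMG"], 3 * a[, "IEMG"], tolerance = 1e-9)
  expect_equal(b[, "WL"], 3 * a[, "WL"], tolerance = 1e-9)
  for (f in c("SSC", "MF", "RMSF", "SE", "FD"))
    expect_equal(b[, f], a[, f], tolerance = 1e-6)
})

test_that("features are stable across halves of a stationary signal", {
  x <- shapedNoiseCarrier(40000, 2000, 80, seed = 14)
  cfg <- windowConfig(fs = 2000)
  v <- featureValues(extractFeatures(x, cfg))
  n <- nrow(v)
  for (f in colnames(v)) {
    m1 <- mean(v[1:(n %/% 2), f]); m2 <- mean(v[(n %/% 2 + 1):n, f])
    expect_lt(abs(m2 - m1) / abs(m1), 0.05)
  }
})

test_that("windowed trends on a default trial match the planted fatigue", {
  tr <- generateTrial(simConfig(duration = 20, seed = 31))
  filt <- trimEdges(preprocessRecording(recording(tr)), 0.25)
  fm <- extractFeatures(signalData(filt)[, 1], windowConfig(fs = 2000),
                        features = c("RMS", "MF"))
  v <- featureValues(fm)
  idx <- seq_len(nrow(v))
  expect_gt(cor(idx, v[, "RMS"], method = "spearman"), 0)
  expect_lt(cor(idx, v[, "MF"], method = "spearman"), 0)
})
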