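test_that("scaled dot-product attention follows the softmax algebra", {
  V <- matrix(c(1, 0, 0, 1), 2)
  # saturation: sharply peaked logits recover V
  big <- scaledDotAttention(50 * diag(2), 50 * diag(2), V)
  expect_equal(big$output, V, tolerance = 1e-6)
  # zero queries give uniform weights -> column means of V
  Vr <- matrix(rnorm(8), 4, 2)
  unif <- scaledDotAttention(matrix(0, 3, 2), matrix(rnorm(8), 4, 2), Vr)
  for (r in 1:3) expect_equal(unif$output[r, ], colMeans(Vr))
  # hand example: weights = softmax(1/sqrt(2), 0)
  att <- scaledDotAttention(matrix(c(1, 0), 1), diag(2),
                            matrix(c(10, 20)))
  w1 <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(att$weights[1, ], c(w1, 1 - w1))
  expect_equal(att$output[1, 1], w1 * 10 + (1 - w1) * 20)
  expect_equal(rowSums(att$weights), 1)
  expect_error(scaledDotAttention(matrix(0, 2, 3), diag(2), diag(2)),
               "dimension")
  expect_error(scaledDotAttention(diag(2), diag(2), matrix(0, 3, 2)),
               "length")
})

test_that("positional encoding is deterministic, bounded and injective", {
  PE <- positionalEncoding(50, 16)
  expect_equal(dim(PE), c(50L, 16L))
  expect_true(all(PE >= -1 & PE <= 1))
  expect_equal(PE[1, seq(1, 15, by = 2)], rep(0, 8))  # sines at pos 0
  expect_equal(PE[1, seq(2, 16, by = 2)], rep(1, 8))  # cosines at pos 0
  expect_equal(nrow(unique(round(PE, 10))), 50L)      # distinct rows
})

test_that("transformer separates separable data and not permuted labels", {
  ds <- makeSeparableDataset(n = 100)
  sp <- splitCV(ds, seed = 1)
  cfg <- testModelConfig(seed = 1)
  mod <- trainTransformer(subsetDataset(ds, sp$trainIdx), cfg)
  pr <- predictProb(mod, subsetDataset(ds, sp$testIdx))
  expect_gte(mean(pr$label == labels2(ds)[sp$testIdx]), 0.95)
  expect_true(all(is.finite(mod@history)))
  expect_lt(mod@history[length(mod@history)], mod@history[1])
  # permuted labels: chance level (average of 2 quick seeds)
  accs <- vapply(1:2, function(s) {
    set.seed(s)
    dsp <- labeledDataset(sequences(ds), sample(labels2(ds)))
    m <- trainTransformer(subsetDataset(dsp, sp$trainIdx),
                          testModelConfig(seed = s, epochs = 10L))
    p <- predictProb(m, subsetDataset(dsp, sp$testIdx))
    mean(p$label == labels2(dsp)[sp$testIdx])
  }, numeric(1))
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})

test_that("training is seeded-deterministic and order-robust", {
  ds <- makeSeparableDataset(n = 60)
  cfg <- testModelConfig(seed = 5, epochs = 8L)
  m1 <- trainTransformer(ds, cfg)
  m2 <- trainTransformer(ds, cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(predictProb(m1, ds)$prob, predictProb(m2, ds)$prob)
  # permuting the sample order changes accuracy by < 3 points
  sp <- splitCV(ds, seed = 2)
  test <- subsetDataset(ds, sp$testIdx)
  train <- subsetDataset(ds, sp$trainIdx)
  set.seed(3)
  perm <- sample(length(sequences(train)))
  trainP <- subsetDataset(train, perm)
  a1 <- mean(predictProb(trainTransformer(train, cfg), test)$label ==
             labels2(test))
  a2 <- mean(predictProb(trainTransformer(trainP, cfg), test)$label ==
             labels2(test))
  expect_lt(abs(a1 - a2), 0.03 + 1e-9)
})

test_that("attention weight rows sum to one at every layer", {
  ds <- makeSeparableDataset(n = 20)
  cfg <- modelConfig(dModel = 16L, nHeads = 4L, nLayers = 2L, ffDim = 32L,
                     epochs = 3L, seed = 1L)
  mod <- trainTransformer(ds, cfg)
  aw <- attentionWeights(mod, subsetDataset(ds, 1:4))
  for (layer in aw) for (seqw in layer) for (headw in seqw) {
    expect_equal(rowSums(headw), rep(1, nrow(headw)), tolerance = 1e-6)
    expect_true(all(headw >= 0))
  }
})

test_that("probability outputs are normalised and threshold-consistent", {
  ds <- makeSeparableDataset(n = 40)
  mod <- trainTransformer(ds, testModelConfig(epochs = 5L))
  pr <- predictProb(mod, ds)
  expect_equal(rowSums(pr$prob), rep(1, 40), tolerance = 1e-6)
  expect_equal(pr$label, as.integer(pr$prob[, "fatigued"] > 0.5))
  empty <- predictProb(mod, list())
  expect_equal(nrow(empty$prob), 0L)
  expect_length(empty$label, 0L)
})

test_that("LSTM and boosted-tree baselines pass the same sanity harness", {
  ds <- makeSeparableDataset(n = 100)
  sp <- splitCV(ds, seed = 1)
  train <- subsetDataset(ds, sp$trainIdx)
  test <- subsetDataset(ds, sp$testIdx)
  yTest <- labels2(test)
  cfg <- testModelConfig(seed = 1)
  for (trainer in list(trainLSTM, trainXGBoost)) {
    mod <- trainer(train, cfg)
    pr <- predictProb(mod, test)
    expect_gte(mean(pr$label == yTest), 0.95)
    expect_equal(rowSums(pr$prob), rep(1, length(yTest)), tolerance = 1e-6)
  }
  # determinism of the tree baseline
  b1 <- predictProb(trainXGBoost(train, cfg), test)$prob
  b2 <- predictProb(trainXGBoost(train, cfg), test)$prob
  expect_identical(b1, b2)
  # chance level on permuted labels for the boosted trees
  set.seed(4)
  dsp <- labeledDataset(sequences(ds), sample(labels2(ds)))
  prp <- predictProb(trainXGBoost(subsetDataset(dsp, sp$trainIdx), cfg),
                     subsetDataset(dsp, sp$testIdx))
  expect_gte(mean(prp$label == labels2(dsp)[sp$testIdx]), 0.2)
  expect_lte(mean(prp$label == labels2(dsp)[sp$testIdx]), 0.8)
})

test_that("single-feature runs reuse the architecture with input width 1", {
  ds <- makeSeparableDataset(n = 40)
  cfg <- testModelConfig(epochs = 5L)
  cfg@featureSubset <- 3L
  mod <- trainTransformer(ds, cfg)
  expect_equal(mod@nFeatures, 1L)
  pr <- predictProb(mod, ds)
  expect_equal(dim(pr$prob), c(40L, 2L))
})
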