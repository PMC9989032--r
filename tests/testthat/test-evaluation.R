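test_that("accuracy is the fraction of positionwise matches", {
  expect_identical(accuracyScore(c("a", "b"), c("a", "b")), 1)
  expect_identical(accuracyScore(c("a", "b", "a", "a"), c("a", "b", "b", "a")),
                   0.75)
  # jointly permuting both lists leaves accuracy unchanged
  p <- c("a", "b", "c", "a", "b"); t0 <- c("a", "c", "c", "b", "b")
  perm <- c(3, 1, 5, 2, 4)
  expect_identical(accuracyScore(p[perm], t0[perm]), accuracyScore(p, t0))
  expect_error(accuracyScore(character(0), character(0)), "non-empty")
  expect_error(accuracyScore(c("a"), c("a", "b")), "equal length")
})

test_that("contribution percent reproduces the published truncated values", {
  expect_identical(contributionPercent(82.182, 71.123), 15.54)
  expect_identical(contributionPercent(76.713, 72.552), 5.73)
  expect_identical(contributionPercent(80, 80), 0)
  # truncation, not rounding: 15.5498... must not become 15.55
  expect_lt(contributionPercent(82.182, 71.123), 15.55)
  # antisymmetric in sign around equality
  expect_identical(contributionPercent(90, 100), -10)
  expect_identical(contributionPercent(110, 100), 10)
  expect_error(contributionPercent(50, 0), "positive")
})

test_that("the classifier head is softmax-normalized and seed-deterministic", {
  cfg <- TrainConfig(epochs = 2, seed = 5)
  clf <- buildClassifier(HeadSpec(outputUnits = 6), cfg)
  img <- generatePestImage("AJ", size = 64, seed = 1)
  p <- predictProba(clf, img)
  expect_length(p, 6)
  expect_lt(abs(sum(p) - 1), 1e-6)
  clf2 <- buildClassifier(HeadSpec(outputUnits = 6), cfg)
  expect_identical(clf@headWeights$W1, clf2@headWeights$W1)
  expect_identical(clf@backbone$W1, clf2@backbone$W1)
})

test_that("pretrained backbones raise a capability error", {
  for (bb in c("vgg16", "vgg19", "resnet50")) {
    cfg <- TrainConfig(backbone = bb)
    expect_error(buildClassifier(HeadSpec(outputUnits = 6), cfg),
                 "pretrained weights")
  }
  # the published input sides are wired into the presets
  expect_identical(TrainConfig(backbone = "vgg16")@inputSide, 224L)
  expect_identical(TrainConfig(backbone = "resnet50")@inputSide, 124L)
})

test_that("training separates a linearly separable two-class problem", {
  d <- separableSet(nPerClass = 30, size = 48, seed = 1)
  sp <- splitTrainVal(d, seed = 2)
  cfg <- TrainConfig(epochs = 20, seed = 3)
  clf <- buildClassifier(HeadSpec(outputUnits = 2), cfg)
  res <- trainAndEvaluate(clf, sp$train, sp$validation, cfg)
  expect_length(trainCurve(res), 20)
  expect_length(valCurve(res), 20)
  expect_gt(finalValAccuracy(res), 0.9)
  expect_identical(finalValAccuracy(res), valCurve(res)[20])
})

test_that("training is reproducible for a fixed seed", {
  d <- separableSet(nPerClass = 8, size = 32, seed = 4)
  sp <- splitTrainVal(d, seed = 5)
  cfg <- TrainConfig(epochs = 4, seed = 6)
  clf <- buildClassifier(HeadSpec(outputUnits = 2), cfg)
  r1 <- trainAndEvaluate(clf, sp$train, sp$validation, cfg)
  r2 <- trainAndEvaluate(clf, sp$train, sp$validation, cfg)
  expect_identical(valCurve(r1), valCurve(r2))
  expect_identical(trainCurve(r1), trainCurve(r2))
})

test_that("class-set mismatches and source leakage are rejected", {
  d <- separableSet(nPerClass = 6, size = 32, seed = 7)
  sp <- splitTrainVal(d, seed = 8)
  cfg <- TrainConfig(epochs = 2, seed = 9)
  clf <- buildClassifier(HeadSpec(outputUnits = 2), cfg)
  # an augmented derivative of a validation image carries its source id:
  # adding it to training must trigger the provenance guard
  leakedRec <- rotateImage(sp$validation[[1]], 30)
  leaked <- PestImageSet(c(sp$train@images, list(leakedRec)),
                         classes = classNames(d))
  expect_error(trainAndEvaluate(clf, leaked, sp$validation, cfg), "leakage")
  other <- PestImageSet(sp$validation@images, classes = c("red", "blue", "x"))
  expect_error(trainAndEvaluate(clf, sp$train, other, cfg), "class set")
})
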