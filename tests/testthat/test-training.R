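test_that("loss functions match their closed forms", {
  gt <- c(rep(1, 10), rep(0, 10))
  expect_equal(diceLoss(gt, gt), 0, tolerance = 1e-6)
  expect_equal(diceLoss(1 - gt, gt), 1, tolerance = 1e-4)
  # uniform 0.5 prediction against a half-foreground target -> 1/3
  expect_equal(diceLoss(rep(0.5, 20), gt), 1 / 3, tolerance = 1e-6)

  expect_equal(iouRegressionLoss(0.8, 0.8), 0)
  expect_equal(iouRegressionLoss(1.0, 0.0), 1.0)
  expect_equal(iouRegressionLoss(0.5, 0.7), 0.04)
})

test_that("the AIS loss masks the distance channels outside the foreground", {
  lab <- labelsFromMasks(list(diskMask(24, 24, 12, 12, 6)))
  target <- computeDistanceTargets(lab)
  expect_equal(aisLoss(target, target), 0, tolerance = 1e-5)

  # inverted foreground, perfect distances -> about 1/3
  inv <- new("DistanceTargets", foreground = 1 - target@foreground,
             center = target@center, boundary = target@boundary)
  expect_equal(aisLoss(inv, target), 1 / 3, tolerance = 1e-3)

  # distance errors confined to background pixels leave the loss unchanged
  bg <- target@foreground == 0
  noisy <- target
  noisy@center[bg] <- 0.123
  noisy@boundary[bg] <- 0.9
  expect_equal(aisLoss(noisy, target), aisLoss(target, target))
})

trainFixture <- function(n = 2L, seed0 = 400L) {
  sets <- lapply(seq_len(n), function(i) {
    generateBlobs2D(testBlobSpec(seed0 + i, nObjects = 4L))
  })
  list(imgs = lapply(sets, `[[`, "image"),
       labs = lapply(sets, `[[`, "labels"))
}

test_that("one interactive iteration keeps the prompt bookkeeping identity", {
  fx <- trainFixture()
  tm <- toyPromptableModel(seed = 2)
  cfg <- trainConfig(patchShape = 64L, nObjectsPerImage = 3L, seed = 5L)
  set.seed(5)
  res <- interactiveTrainIteration(tm, fx$imgs, fx$labs, cfg)
  expect_true(is.finite(res$loss))
  expect_gt(res$loss, 0)
  tr <- res$trace
  # at sub-iteration k: 1 + 2k points (point start) or 2k points + box
  expect_true(all(tr$nPoints[!tr$hasBox] == 1 + 2 * tr$subIteration[!tr$hasBox]))
  expect_true(all(tr$nPoints[tr$hasBox] == 2 * tr$subIteration[tr$hasBox]))
  # the box, once given, is never dropped within an object
  for (key in unique(paste(tr$image, tr$object))) {
    expect_length(unique(tr$hasBox[paste(tr$image, tr$object) == key]), 1L)
  }
  # no mask prompt at sub-iteration 0
  expect_true(all(!tr$usedMaskPrompt[tr$subIteration == 0]))
})

test_that("mask prompts are sampled at the configured probability", {
  fx <- trainFixture()
  tm <- toyPromptableModel(seed = 2)
  cfg0 <- trainConfig(patchShape = 64L, maskPromptProbability = 0,
                      nObjectsPerImage = 2L)
  set.seed(1)
  r0 <- interactiveTrainIteration(tm, fx$imgs, fx$labs, cfg0)
  expect_true(all(!r0$trace$usedMaskPrompt))

  # frequency about 0.5 over >= 1000 correction sub-iterations
  cfg <- trainConfig(patchShape = 64L, maskPromptProbability = 0.5,
                     nObjectsPerImage = 4L)
  used <- logical()
  set.seed(2)
  tm2 <- toyPromptableModel(seed = 2)
  for (rep in 1:5) {
    r <- interactiveTrainIteration(tm2, fx$imgs, fx$labs, cfg)
    used <- c(used, r$trace$usedMaskPrompt[r$trace$subIteration > 0])
  }
  n <- length(used)
  expect_gte(n, 280 * 0.9)
  phat <- mean(used)
  ci <- 3 * sqrt(0.25 / n)   # generous binomial band
  expect_lt(abs(phat - 0.5), ci + 0.08)
})

test_that("AIS iterations reduce the loss when overfitting a fixed batch", {
  fx <- trainFixture(1L, seed0 = 410L)
  tm <- toyPromptableModel(seed = 3)
  cfg <- trainConfig(patchShape = 64L, learningRate = 5e-3, seed = 6L)
  ns <- asNamespace("promptSeg")
  opt <- ns$adamInit(tm@weights)
  set.seed(6)
  first <- aisTrainIteration(tm, fx$imgs, fx$labs, cfg, opt)$loss
  last <- first
  for (i in 1:60) {
    last <- aisTrainIteration(tm, fx$imgs, fx$labs, cfg, opt)$loss
  }
  expect_lt(last, first * 0.8)
})

test_that("frozen parameter groups stay bit-identical through training", {
  fx <- trainFixture()
  tm <- toyPromptableModel(seed = 4)
  before <- promptSeg:::weightsAsList(tm)
  cfg <- trainConfig(patchShape = 64L, maxEpochs = 2L,
                     freeze = c("encoder", "prompt_encoder"), seed = 8L)
  fitPromptable(tm, fx$imgs, fx$labs, fx$imgs, fx$labs, cfg)
  after <- promptSeg:::weightsAsList(tm)
  frozenParams <- c("W1", "b1", "W2", "b2", "Wp", "bp")
  for (nm in frozenParams) {
    expect_identical(after[[nm]], before[[nm]], label = nm)
  }
  # non-frozen groups did move
  expect_false(identical(after$W3, before$W3))
  expect_false(identical(after$Wa, before$Wa))
})

test_that("validation is deterministic and rewards a better AIS head", {
  fx <- trainFixture(1L)
  lab <- fx$labs[[1]]
  om <- oracleModel(lab)
  cfg <- trainConfig(patchShape = 64L)
  v1 <- validateModel(om, fx$imgs, fx$labs, cfg, seed = 3L)
  v2 <- validateModel(om, fx$imgs, fx$labs, cfg, seed = 3L)
  expect_identical(v1, v2)
  # oracle: interactive Dice component is exactly 1, AIS component ideal
  expect_equal(v1, 2, tolerance = 1e-5)
  # an untrained toy model scores strictly less
  tm <- toyPromptableModel(seed = 5)
  expect_lt(validateModel(tm, fx$imgs, fx$labs, cfg, seed = 3L), v1)
})

test_that("training runs are reproducible and early stopping works", {
  fx <- trainFixture()
  cfg <- trainConfig(patchShape = 64L, maxEpochs = 3L, seed = 21L)
  tmA <- toyPromptableModel(seed = 9)
  tmB <- toyPromptableModel(seed = 9)
  stA <- fitPromptable(tmA, fx$imgs, fx$labs, fx$imgs, fx$labs, cfg)
  stB <- fitPromptable(tmB, fx$imgs, fx$labs, fx$imgs, fx$labs, cfg)
  expect_equal(stA@losses$maskLoss, stB@losses$maskLoss)
  expect_equal(stA@valHistory, stB@valHistory)
  expect_identical(promptSeg:::weightsAsList(tmA),
                   promptSeg:::weightsAsList(tmB))
  # loss bookkeeping: recorded per-iteration losses are finite
  expect_true(all(is.finite(stA@losses$maskLoss)))
  expect_true(all(is.finite(stA@losses$aisLoss)))
  expect_error(fitPromptable(tmA, list(), list(), fx$imgs, fx$labs, cfg),
               "empty")

  # frozen validation metric (zero learning rate) triggers early stopping
  cfg2 <- trainConfig(patchShape = 64L, maxEpochs = 30L, learningRate = 0,
                      earlyStoppingPatience = 3L, seed = 22L)
  tmC <- toyPromptableModel(seed = 9)
  stC <- fitPromptable(tmC, fx$imgs, fx$labs, fx$imgs, fx$labs, cfg2)
  expect_equal(length(stC@valHistory), 4L)  # 1 improvement + 3 flat epochs
})
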