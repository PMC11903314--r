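# contract conformance for both reference models, oracle semantics, the
# embedding cache and checkpoint round-trips

contractModels <- function() {
  lab <- labelsFromMasks(list(diskMask(48, 48, 14, 14, 6),
                              diskMask(48, 48, 34, 30, 7)))
  img <- 0.2 + 0.6 * (lab > 0)
  list(oracle = oracleModel(lab), toy = toyPromptableModel(seed = 1),
       image = img, labels = lab)
}

test_that("both models fulfil the promptable contract", {
  fx <- contractModels()
  for (nm in c("oracle", "toy")) {
    model <- fx[[nm]]
    emb <- embedImage(model, fx$image)
    expect_s4_class(emb, "ImageEmbedding")
    prompts <- promptSet(points = c(14, 14))
    single <- predictMasks(model, emb, prompts, multimask = FALSE)
    multi <- predictMasks(model, emb, prompts, multimask = TRUE)
    expect_length(single, 1L)
    expect_length(multi, 3L)
    for (p in c(single, multi)) {
      expect_identical(dim(p@logits), dim(fx$image))
      expect_true(all(is.finite(p@logits)))
      expect_gte(p@iouEstimate, 0)
      expect_lte(p@iouEstimate, 1)
    }
    # embedding is prompt-independent: recompute with other prompts around
    emb2 <- embedImage(model, fx$image)
    expect_equal(emb2@features, emb@features)
  }
})

test_that("the exact oracle returns the prompted object with IoU 1", {
  fx <- contractModels()
  emb <- embedImage(fx$oracle, fx$image)
  p <- predictMasks(fx$oracle, emb, promptSet(points = c(34, 30)))[[1]]
  expect_identical(p@logits > 0, fx$labels == 2L)
  expect_equal(p@iouEstimate, 1.0)

  # box prompt around object 1
  b <- boxFromMask(fx$labels == 1L)
  pb <- predictMasks(fx$oracle, emb, promptSet(box = b))[[1]]
  expect_identical(pb@logits > 0, fx$labels == 1L)

  # prompt on background -> empty mask, estimate 0
  p0 <- predictMasks(fx$oracle, emb, promptSet(points = c(1, 1)))[[1]]
  expect_false(any(p0@logits > 0))
  expect_equal(p0@iouEstimate, 0)

  # a negative point inside the target object empties the prediction
  pneg <- predictMasks(fx$oracle, emb,
                       promptSet(points = rbind(c(34, 30), c(34, 31)),
                                 positive = c(TRUE, FALSE)))[[1]]
  expect_false(any(pneg@logits > 0))
})

test_that("dilate/erode oracles report the true IoU of the transform", {
  lab <- labelsFromMasks(list(diskMask(40, 40, 20, 20, 8)))
  img <- 0.2 + 0.6 * (lab > 0)
  od <- oracleModel(lab, "dilate", k = 2L)
  emb <- embedImage(od, img)
  p <- predictMasks(od, emb, promptSet(points = c(20, 20)))[[1]]
  mask <- p@logits > 0
  expect_true(all(mask[lab == 1L]))       # superset of the object
  expect_gt(sum(mask), sum(lab == 1L))
  expect_equal(p@iouEstimate, maskIoU(mask, lab == 1L))
  expect_lt(p@iouEstimate, 1)

  oe <- oracleModel(lab, "erode", k = 2L)
  pe <- predictMasks(oe, embedImage(oe, img),
                     promptSet(points = c(20, 20)))[[1]]
  expect_true(all(lab[pe@logits > 0] == 1L))  # subset
  expect_lt(sum(pe@logits > 0), sum(lab == 1L))
})

test_that("the embedding cache computes once and survives corruption", {
  fx <- contractModels()
  store <- tempfile(fileext = ".rds")
  cache <- embeddingCache(store)
  e1 <- getOrComputeEmbedding(cache, fx$toy, fx$image, key = "k1")
  e2 <- getOrComputeEmbedding(cache, fx$toy, fx$image, key = "k1")
  expect_equal(cacheMisses(cache), 1L)       # second call hit the cache
  expect_equal(e2@features, e1@features)      # bit-identical to fresh
  fresh <- embedImage(fx$toy, fx$image)
  expect_equal(e2@features, fresh@features)

  e3 <- getOrComputeEmbedding(cache, fx$toy, fx$image, key = "k2")
  expect_equal(cacheMisses(cache), 2L)       # different key, new entry

  writeLines("garbage", store)                # corrupt the archive
  expect_warning(
    e4 <- getOrComputeEmbedding(cache, fx$toy, fx$image, key = "k1"),
    "corrupt")
  expect_equal(e4@features, e1@features)
})

test_that("toy checkpoints round-trip predictions exactly", {
  fx <- contractModels()
  f <- tempfile(fileext = ".rds")
  saveToyModel(fx$toy, f)
  back <- loadToyModel(f)
  emb1 <- embedImage(fx$toy, fx$image)
  emb2 <- embedImage(back, fx$image)
  pr1 <- predictMasks(fx$toy, emb1, promptSet(points = c(14, 14)))[[1]]
  pr2 <- predictMasks(back, emb2, promptSet(points = c(14, 14)))[[1]]
  expect_identical(pr1@logits, pr2@logits)
  expect_identical(pr1@iouEstimate, pr2@iouEstimate)
})

test_that("toy model exposes the four trainable parameter groups", {
  expect_setequal(trainableGroups(toyPromptableModel()),
                  c("encoder", "prompt_encoder", "mask_decoder",
                    "ais_decoder"))
  expect_length(trainableGroups(oracleModel(matrix(0L, 4, 4))), 0L)
  expect_error(toyPromptableModel(C1 = 0L), ">= 1")
})

test_that("backpropagated gradients match finite differences", {
  ns <- asNamespace("promptSeg")
  set.seed(4)
  arch <- ns$toyArch(4L, 6L, 4L, 6L, 4L, 6)
  w <- ns$toyInitWeights(arch, 5L)
  g <- ns$geom(16L, 16L, 4L)
  X0 <- matrix(runif(16 * 16 * 3), 256, 3)
  target <- as.numeric(matrix(runif(256) > 0.6, 16, 16))
  M <- ns$rasterPrompts(promptSet(points = c(8, 8), box = c(4, 4, 12, 12)),
                        g, 6)
  lossFn <- function() {
    enc <- ns$encForward(w, X0, g)
    dec <- ns$decForward(w, enc$E, M, g, enc$H1)
    p <- ns$sigmoid(dec$Lfull[, 1])
    diceLoss(p, target) + iouRegressionLoss(dec$iouEst[1], 0.4)
  }
  enc <- ns$encForward(w, X0, g)
  dec <- ns$decForward(w, enc$E, M, g, enc$H1)
  grads <- ns$zeroGrads(w)
  p <- ns$sigmoid(dec$Lfull[, 1])
  dZ <- ns$diceLossGrad(p, target) * p * (1 - p)
  dLfull <- matrix(0, 256, 4)
  dLfull[, 1] <- dZ
  est <- dec$iouEst[1]
  dIou <- numeric(4)
  dIou[1] <- 2 * (est - 0.4) * est * (1 - est)
  bk <- ns$decBackward(w, dec, dLfull, dIou, g, grads)
  ns$encBackward(w, enc, bk$dE, g, grads, bk$dH1)
  eps <- 1e-6
  for (nm in c("W1", "b1", "W2", "Wp", "W3", "b3", "W4", "b4", "W5",
               "Wi", "bi")) {
    for (i in c(1L, length(w[[nm]]))) {
      orig <- w[[nm]][i]
      w[[nm]][i] <- orig + eps
      up <- lossFn()
      w[[nm]][i] <- orig - eps
      dn <- lossFn()
      w[[nm]][i] <- orig
      expect_equal(grads[[nm]][i], (up - dn) / (2 * eps),
                   tolerance = 1e-4, label = paste("grad", nm, i))
    }
  }
})
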