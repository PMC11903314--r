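test_that("grid points are evenly spaced with a half-cell offset", {
  pts <- gridPoints(c(64L, 64L), 2L)
  expect_equal(nrow(pts), 4L)
  expect_setequal(paste(pts[, 1], pts[, 2]),
                  c("17 17", "17 49", "49 17", "49 49"))

  ctr <- gridPoints(c(64L, 64L), 1L)
  expect_equal(nrow(ctr), 1L)
  expect_equal(as.numeric(ctr[1, ]), c(33, 33))

  pts2 <- gridPoints(c(50L, 70L), 7L)
  expect_true(all(pts2[, 1] >= 1 & pts2[, 1] <= 50))
  expect_true(all(pts2[, 2] >= 1 & pts2[, 2] <= 70))
  expect_equal(nrow(pts2), 49L)
})

test_that("the stability score compares offset thresholdings", {
  step <- matrix(-10, 20, 20)
  step[5:15, 5:15] <- 10
  expect_equal(stabilityScore(step, 1), 1.0)

  uniform <- matrix(0.5, 10, 10)
  expect_equal(stabilityScore(uniform, 1), 0.0)  # empty vs full

  noisy <- matrix(rnorm(100), 10, 10)
  expect_equal(stabilityScore(noisy, 0), 1.0)    # identical masks
})

amgFixture <- function() {
  lab <- labelsFromMasks(list(diskMask(64, 64, 16, 16, 8),
                              diskMask(64, 64, 44, 20, 9),
                              diskMask(64, 64, 28, 48, 8)))
  img <- 0.2 + 0.6 * (lab > 0)
  list(lab = lab, img = img, model = oracleModel(lab))
}

test_that("AMG with an exact oracle recovers every object", {
  fx <- amgFixture()
  emb <- embedImage(fx$model, fx$img)
  # grid spacing 64/8 = 8 px, denser than the smallest object (r = 8)
  cfg <- amgConfig(pointsPerSide = 8L, iouThreshold = 0.8,
                   stabilityThreshold = 0.8)
  cands <- amgGenerate(fx$model, emb, cfg)
  expect_gt(length(cands), 0L)
  for (id in objectIds(fx$lab)) {
    ious <- vapply(cands, function(cand) maskIoU(cand@mask, fx$lab == id),
                   numeric(1))
    expect_equal(max(ious), 1.0, label = paste("object", id))
  }
  seg <- amgSegment(fx$model, emb, cfg)
  expect_equal(meanSegmentationAccuracy(seg, fx$lab), 1.0)

  # impossible threshold empties the output
  expect_length(amgGenerate(fx$model, emb,
                            amgConfig(pointsPerSide = 8L,
                                      iouThreshold = 1.01)), 0L)

  # object-free image: nothing survives the size filter
  empty <- oracleModel(matrix(0L, 32, 32))
  embE <- embedImage(empty, matrix(0.2, 32, 32))
  expect_length(amgGenerate(empty, embE, amgConfig(pointsPerSide = 4L)), 0L)
})

test_that("filtering is monotone in both thresholds", {
  fx <- amgFixture()
  emb <- embedImage(fx$model, fx$img)
  base <- amgConfig(pointsPerSide = 6L, iouThreshold = 0,
                    stabilityThreshold = 0)
  all <- amgGenerate(fx$model, emb, base)
  n <- function(iouT, stabT) {
    length(amgGenerate(fx$model, emb,
                       amgConfig(pointsPerSide = 6L, iouThreshold = iouT,
                                 stabilityThreshold = stabT)))
  }
  expect_true(n(0.5, 0) <= length(all))
  expect_true(n(0.9, 0) <= n(0.5, 0))
  expect_true(n(0, 0.9) <= n(0, 0.5))
})

mkCand <- function(mask, score) {
  new("MaskCandidate", mask = mask, iouEstimate = score, stability = 1,
      sourcePoint = c(1, 1))
}

test_that("NMS keeps the best of duplicates and respects the chain case", {
  m <- diskMask(20, 20, 10, 10, 5)
  kept <- nmsMasks(list(mkCand(m, 0.9), mkCand(m, 0.8)), 0.7)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]@iouEstimate, 0.9)

  d1 <- diskMask(40, 40, 10, 10, 5)
  d2 <- diskMask(40, 40, 30, 30, 5)
  expect_length(nmsMasks(list(mkCand(d1, 0.9), mkCand(d2, 0.8)), 0.7), 2L)

  # chain: B overlaps A above the threshold, C overlaps B above but A
  # below the threshold; greedy by score keeps {A, C}
  A <- matrix(FALSE, 1, 40); A[1, 1:10] <- TRUE
  B <- matrix(FALSE, 1, 40); B[1, 2:11] <- TRUE   # IoU(A,B) = 9/11 = .82
  C <- matrix(FALSE, 1, 40); C[1, 3:12] <- TRUE   # IoU(B,C) = .82,
                                                  # IoU(A,C) = 8/12 = .67
  kept2 <- nmsMasks(list(mkCand(A, 0.9), mkCand(B, 0.85), mkCand(C, 0.8)),
                    0.7)
  expect_length(kept2, 2L)
  expect_equal(vapply(kept2, function(k) k@iouEstimate, numeric(1)),
               c(0.9, 0.8))

  # antichain property on a fuzzed set
  set.seed(3)
  cands <- lapply(1:25, function(i) {
    mkCand(diskMask(32, 32, sample(8:24, 1), sample(8:24, 1),
                    sample(4:7, 1)), runif(1))
  })
  keptF <- nmsMasks(cands, 0.5)
  for (i in seq_along(keptF)) {
    for (j in seq_len(i - 1L)) {
      expect_lte(maskIoU(keptF[[i]]@mask, keptF[[j]]@mask), 0.5)
    }
  }
})

test_that("label rendering resolves overlaps by score", {
  d1 <- diskMask(30, 30, 14, 14, 6)
  d2 <- diskMask(30, 30, 16, 16, 6)
  lab <- candidatesToLabels(list(mkCand(d1, 0.6), mkCand(d2, 0.9)),
                            c(30L, 30L))
  # contested pixels belong to the higher-score mask (painted last)
  both <- d1 & d2
  expect_true(all(lab[both] == lab[which(d2 & !d1)[1]]))
  expect_length(objectIds(lab), 2L)

  disj <- candidatesToLabels(list(mkCand(diskMask(20, 20, 5, 5, 3), 0.5),
                                  mkCand(diskMask(20, 20, 15, 15, 3), 0.6)),
                             c(20L, 20L))
  expect_length(objectIds(disj), 2L)
  expect_identical(candidatesToLabels(list(), c(8L, 8L)), matrix(0L, 8, 8))
})

test_that("AMG grid search scores every grid point and finds the permissive corner", {
  fx <- amgFixture()
  base <- amgConfig(pointsPerSide = 6L)
  gs <- gridSearchAMG(fx$model, list(fx$img), list(fx$lab),
                      iouGrid = c(0.5, 0.9), stabilityGrid = c(0.5, 0.9),
                      base = base)
  expect_equal(nrow(gs$table), 4L)
  # exact-oracle masks carry estimate 1.0: every corner reaches mSA 1.0
  expect_equal(max(gs$table$meanMSA), 1.0)
  best <- which.max(gs$table$meanMSA)
  expect_equal(gs$config@iouThreshold, gs$table$iou[best])

  gs1 <- gridSearchAMG(fx$model, list(fx$img), list(fx$lab),
                       iouGrid = 0.7, stabilityGrid = 0.8, base = base)
  expect_equal(nrow(gs1$table), 1L)
  expect_equal(gs1$config@iouThreshold, 0.7)
  expect_equal(gs1$config@stabilityThreshold, 0.8)
})
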