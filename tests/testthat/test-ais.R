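test_that("distance targets follow the channel conventions", {
  # empty labels
  dt0 <- computeDistanceTargets(matrix(0L, 8, 8))
  expect_true(all(dt0@foreground == 0))
  expect_true(all(dt0@center == 1))
  expect_true(all(dt0@boundary == 0))

  # single-pixel object: degenerate normalization
  lab1 <- matrix(0L, 7, 7)
  lab1[4, 4] <- 1L
  dt1 <- computeDistanceTargets(lab1)
  expect_equal(dt1@foreground[4, 4], 1)
  expect_equal(dt1@center[4, 4], 0)
  expect_equal(dt1@boundary[4, 4], 1)

  # 11x11 square: closed-form Euclidean distances
  lab2 <- matrix(0L, 15, 15)
  lab2[3:13, 3:13] <- 1L
  dt2 <- computeDistanceTargets(lab2)
  expect_equal(dt2@center[8, 8], 0)                 # centroid pixel
  expect_equal(dt2@center[3, 3], 1)                 # corners at max distance
  expect_equal(dt2@center[13, 13], 1)
  expect_equal(dt2@boundary[8, 8], 1)               # innermost pixel
  # mid-edge center distance: 5 / (5 sqrt 2)
  expect_equal(dt2@center[3, 8], 5 / sqrt(50))
  # background conventions
  expect_equal(dt2@center[1, 1], 1)
  expect_equal(dt2@boundary[1, 1], 0)
  # channels bounded
  for (ch in list(dt2@foreground, dt2@center, dt2@boundary)) {
    expect_true(all(ch >= 0 & ch <= 1))
  }
})

test_that("ideal channels decode back to the original instances", {
  # two disjoint blobs
  lab <- labelsFromMasks(list(diskMask(48, 48, 14, 14, 6),
                              diskMask(48, 48, 34, 32, 8)))
  seg <- aisSegment(computeDistanceTargets(lab))
  expect_length(objectIds(seg), 2L)
  expect_equal(meanSegmentationAccuracy(seg, lab), 1.0)

  # all-background foreground -> empty segmentation
  dt <- computeDistanceTargets(matrix(0L, 16, 16))
  expect_identical(aisSegment(dt), matrix(0L, 16, 16))

  # two touching blobs split at the interface
  lab2 <- touchingSquares()
  seg2 <- aisSegment(computeDistanceTargets(lab2))
  expect_length(objectIds(seg2), 2L)
  expect_equal(meanSegmentationAccuracy(seg2, lab2), 1.0)
})

test_that("round trip reaches mSA 1.0 on random synthetic images", {
  for (seed in 1:10) {
    lab <- generateBlobs2D(testBlobSpec(seed, touchingFraction = 0.4))$labels
    seg <- aisSegment(computeDistanceTargets(lab))
    expect_equal(meanSegmentationAccuracy(seg, lab), 1.0,
                 label = paste("seed", seed))
  }
})

test_that("instances are disjoint, inside the mask, and monotone in the seed threshold", {
  lab <- generateBlobs2D(testBlobSpec(33, touchingFraction = 0.4))$labels
  dt <- computeDistanceTargets(lab)
  seg <- aisSegment(dt)
  expect_true(all(seg[dt@foreground <= 0.5] == 0L))
  nAt <- function(tc) {
    length(objectIds(aisSegment(dt, aisConfig(centerThreshold = tc))))
  }
  counts <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), nAt, numeric(1))
  expect_true(all(diff(counts) >= 0))  # stricter seeds never add instances
})

test_that("small instances are removed by the size filter", {
  lab <- matrix(0L, 20, 20)
  lab[2:3, 2:3] <- 1L               # 4 px object
  lab[10:16, 10:16] <- 2L
  seg <- aisSegment(computeDistanceTargets(lab),
                    aisConfig(minObjectSize = 10))
  expect_length(objectIds(seg), 1L)
})

test_that("AIS grid search returns the argmax of its own table", {
  labs <- lapply(1:3, function(s) {
    generateBlobs2D(testBlobSpec(s, touchingFraction = 0.3))$labels
  })
  preds <- lapply(labs, computeDistanceTargets)
  gs <- gridSearchAIS(preds, labs, centerGrid = c(0.3, 0.5, 0.7),
                      boundaryGrid = c(0.3, 0.5, 0.7))
  expect_equal(nrow(gs$table), 9L)
  best <- which.max(gs$table$meanMSA)
  expect_equal(gs$config@centerThreshold, gs$table$center[best])
  expect_equal(gs$config@boundaryThreshold, gs$table$boundary[best])
  # ideal channels: the known-good default corner scores 1.0
  expect_equal(max(gs$table$meanMSA), 1.0)

  # single-point grid returns that config
  gs1 <- gridSearchAIS(preds[1], labs[1], centerGrid = 0.4,
                       boundaryGrid = 0.6)
  expect_equal(nrow(gs1$table), 1L)
  expect_equal(gs1$config@centerThreshold, 0.4)
  expect_equal(gs1$config@boundaryThreshold, 0.6)
})
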