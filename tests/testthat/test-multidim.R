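sphereFixture <- function(seed = 5) {
  sp <- syntheticSpec(shape = c(21L, 48L, 48L), nObjects = 1L,
                      radiusRange = c(8, 8), seed = seed)
  vol <- generateVolume(sp)
  vol$models <- lapply(seq_len(21L), function(z) oracleModel(vol$labels[z, , ]))
  vol
}

voxelIoU <- function(a, b) sum(a & b) / sum(a | b)

test_that("interactive volume segmentation follows a sphere slice by slice", {
  fx <- sphereFixture()
  eq <- 11L  # equator slice
  w <- which(fx$labels[eq, , ] == 1L, arr.ind = TRUE)
  seedPrompt <- promptSet(points = matrix(round(colMeans(w)), 1, 2))
  # pole cross-sections shrink to single pixels, so complete coverage
  # needs a permissive slice-to-slice stopping threshold
  seg <- segmentObjectInVolume(fx$models, fx$image, eq, seedPrompt,
                               stopIou = 0.01)
  expect_equal(voxelIoU(seg > 0L, fx$labels > 0L), 1.0)

  # stopIou above 1 restricts the result to the seed slice
  seg1 <- segmentObjectInVolume(fx$models, fx$image, eq, seedPrompt,
                                stopIou = 1.01)
  occupied <- which(apply(seg1 > 0L, 1, any))
  expect_equal(occupied, eq)

  # seeding on background errors with context
  expect_error(segmentObjectInVolume(fx$models, fx$image, eq,
                                     promptSet(points = c(1, 1))),
               "seed slice")
})

cylinderSlices <- function(Z = 10L, centers = list(c(16, 16))) {
  lapply(seq_len(Z), function(z) {
    labelsFromMasks(lapply(centers, function(ct) {
      diskMask(40, 40, ct[1], ct[2], 6)
    }))
  })
}

test_that("slice merging links cylinders and respects extent filtering", {
  one <- cylinderSlices(10L)
  merged <- mergeSliceSegmentations(one, linkIou = 0.5, minExtent = 1L)
  expect_length(objectIds(merged), 1L)
  expect_true(all(apply(merged > 0L, 1, any)))

  # two parallel cylinders never merge (cross IoU 0)
  two <- cylinderSlices(8L, list(c(12, 12), c(28, 28)))
  merged2 <- mergeSliceSegmentations(two)
  expect_length(objectIds(merged2), 2L)
  for (z in 1:8) {
    ids <- unique(merged2[z, , ][merged2[z, , ] > 0])
    expect_length(ids, 2L)
  }
  # an id refers to the same column of the cylinder in every slice
  expect_equal(length(unique(merged2[, 12, 12][merged2[, 12, 12] > 0])), 1L)

  # a single-slice mask is removed under minExtent = 2
  spur <- cylinderSlices(5L)
  spur[[3]][35:38, 35:38] <- 99L
  merged3 <- mergeSliceSegmentations(spur, minExtent = 2L)
  expect_length(objectIds(merged3), 1L)
  expect_true(all(merged3[3, 35:38, 35:38] == 0L))

  # merging only relabels: per-slice partitions are preserved
  m2z <- merged2[3, , ]
  orig <- relabelConsecutive(two[[3]])
  expect_identical(m2z > 0L, orig > 0L)
  expect_equal(length(objectIds(m2z)), length(objectIds(orig)))
})

test_that("slice merging is direction symmetric", {
  fx <- sphereFixture()
  slices <- lapply(seq_len(21L), function(z) fx$labels[z, , ])
  fwd <- mergeSliceSegmentations(slices)
  bwd <- mergeSliceSegmentations(rev(slices))
  expect_equal(length(objectIds(fwd)), length(objectIds(bwd)))
  expect_identical(fwd > 0L, bwd[rev(seq_len(21L)), , ] > 0L)
})

test_that("automatic volume segmentation round-trips ideal channels", {
  sp <- syntheticSpec(shape = c(16L, 48L, 48L), nObjects = 2L,
                      radiusRange = c(6, 6), seed = 8)
  vol <- generateVolume(sp)
  models <- lapply(seq_len(16L), function(z) oracleModel(vol$labels[z, , ]))
  # keep single-pixel pole cross-sections and link them to their chains
  seg <- segmentVolumeAuto(models, vol$image, mode = "ais",
                           config = aisConfig(minObjectSize = 1),
                           linkIou = 0.02)
  expect_length(objectIds(seg), 2L)
  # voxel-level agreement per object
  for (id in objectIds(seg)) {
    overlaps <- vapply(objectIds(vol$labels), function(gid) {
      voxelIoU(seg == id, vol$labels == gid)
    }, numeric(1))
    expect_equal(max(overlaps), 1.0)
  }

  # empty volume -> empty segmentation
  empty <- array(0L, dim = c(4L, 24L, 24L))
  mEmpty <- lapply(1:4, function(z) oracleModel(empty[1, , ]))
  segE <- segmentVolumeAuto(mEmpty, array(0.2, dim = c(4, 24, 24)), "ais")
  expect_true(all(segE == 0L))

  # a one-slice volume reduces to the 2D result
  one <- array(vol$image[8, , ], dim = c(1, 48, 48))
  seg1 <- segmentVolumeAuto(list(models[[8]]), one, "ais")
  d2 <- aisSegment(computeDistanceTargets(vol$labels[8, , ]))
  expect_equal(meanSegmentationAccuracy(seg1[1, , ], d2), 1.0)
})

test_that("tracking follows drifting objects and stops on disappearance", {
  sp <- syntheticSpec(shape = c(6L, 64L, 64L), nObjects = 1L,
                      radiusRange = c(6, 6), driftPerFrame = 2, seed = 12)
  ts <- generateTimeseries(sp)
  models <- lapply(seq_len(6L), function(fr) oracleModel(ts$labels[fr, , ]))
  w <- which(ts$labels[1, , ] == 1L, arr.ind = TRUE)
  tr <- trackObject(models, ts$image, 1L,
                    promptSet(points = matrix(round(colMeans(w)), 1, 2)))
  expect_equal(nrow(tr$table), 6L)
  for (fr in 1:6) {
    expect_equal(maskIoU(tr$labels[fr, , ] > 0L, ts$labels[fr, , ] == 1L),
                 1.0)
  }

  # the object disappears at frame 4: the track ends at frame 3
  lab2 <- ts$labels
  lab2[4:6, , ] <- 0L
  models2 <- lapply(seq_len(6L), function(fr) oracleModel(lab2[fr, , ]))
  tr2 <- trackObject(models2, ts$image, 1L,
                     promptSet(points = matrix(round(colMeans(w)), 1, 2)))
  expect_equal(max(tr2$table$frame), 3L)

  # a jump larger than the object ends the track early
  jump <- array(0L, dim = c(3L, 64L, 64L))
  jump[1, , ][diskMask(64, 64, 16, 16, 5)] <- 1L
  jump[2, , ][diskMask(64, 64, 48, 48, 5)] <- 1L
  jump[3, , ][diskMask(64, 64, 48, 48, 5)] <- 1L
  img <- array(0.2 + 0.6 * (jump > 0), dim = dim(jump))
  models3 <- lapply(1:3, function(fr) oracleModel(jump[fr, , ]))
  tr3 <- trackObject(models3, img, 1L, promptSet(points = c(16, 16)),
                     stopIou = 0.5)
  expect_equal(max(tr3$table$frame), 1L)
})
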