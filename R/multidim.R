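## multidim: volumetric segmentation and tracking built from the 2D
## engine — interactive mask projection across slices/frames and
## automatic per-slice segmentation merged across slices.

sliceModel <- function(model, z) if (is.list(model)) model[[z]] else model

## prompts derived from the previous slice's prediction: its bounding box,
## the mask fed back as a low-resolution prompt, and optionally the mask
## centroid as a positive point.
projectionPrompts <- function(logits, scale, addCentroidPoint = FALSE) {
  mask <- logits > 0
  box <- boxFromMask(mask)
  lp <- padToScale(logits, scale)
  mp <- downsampleLogits(lp, geom(nrow(lp), ncol(lp), scale))
  pts <- NULL
  if (addCentroidPoint) {
    w <- which(mask, arr.ind = TRUE)
    ctr <- round(colMeans(w))
    if (!mask[ctr[1L], ctr[2L]]) {
      ctr <- as.numeric(w[which.min((w[, 1L] - ctr[1L])^2 +
                                    (w[, 2L] - ctr[2L])^2), ])
    }
    pts <- matrix(ctr, 1L, 2L)
  }
  promptSet(points = pts, positive = TRUE, box = box, maskPrompt = mp)
}

#' Segment one object through a volume by mask projection
#'
#' The object is segmented on the seed slice from the given prompts; the
#' prediction is then projected to the adjacent slices (bounding box +
#' mask prompt, optionally the centroid as a positive point) and the model
#' re-run, marching up and down from the seed. A direction stops when the
#' new mask is empty or its IoU with the previous slice's mask falls below
#' `stopIou`.
#'
#' @param model a [PromptableModel-class], or a list with one model per
#'   slice (e.g. per-slice oracles).
#' @param volume numeric Z x H x W array.
#' @param seedSliceIndex slice carrying the seed prompts.
#' @param seedPrompts a [PromptSet-class] identifying the object there.
#' @param stopIou stopping threshold in \[0, 1\] (values > 1 stop
#'   immediately after the seed slice).
#' @param addCentroidPoint include the previous mask's centroid as a
#'   positive point in the projected prompts.
#' @return integer Z x H x W array with the object as id 1.
#' @export
segmentObjectInVolume <- function(model, volume, seedSliceIndex,
                                  seedPrompts, stopIou = 0.5,
                                  addCentroidPoint = FALSE) {
  Z <- dim(volume)[1L]
  out <- array(0L, dim = dim(volume))
  m0 <- sliceModel(model, seedSliceIndex)
  emb0 <- embedImage(m0, volume[seedSliceIndex, , ])
  pred0 <- predictMasks(m0, emb0, seedPrompts)[[1L]]
  if (!any(pred0@logits > 0))
    stop("empty prediction on seed slice ", seedSliceIndex,
         "; seed prompts do not identify an object")
  plane <- out[seedSliceIndex, , ]
  plane[pred0@logits > 0] <- 1L
  out[seedSliceIndex, , ] <- plane
  march <- function(dir) {
    prev <- pred0@logits
    z <- seedSliceIndex + dir
    while (z >= 1L && z <= Z) {
      mz <- sliceModel(model, z)
      prompts <- projectionPrompts(prev, scaleOf(mz), addCentroidPoint)
      emb <- embedImage(mz, volume[z, , ])
      pred <- predictMasks(mz, emb, prompts)[[1L]]
      newMask <- pred@logits > 0
      if (!any(newMask) || maskIoU(newMask, prev > 0) < stopIou) break
      plane <- out[z, , ]
      plane[newMask] <- 1L
      out[z, , ] <<- plane
      prev <- pred@logits
      z <- z + dir
    }
  }
  march(+1L)
  march(-1L)
  out
}

scaleOf <- function(model) {
  if (is(model, "ToyPromptableModel")) model@arch$scale else 1L
}

#' Merge per-slice segmentations into a volume segmentation
#'
#' Consecutive slices are linked bipartitely: instance pairs with IoU
#' above `linkIou` are matched greedily by descending IoU, one-to-one;
#' linked chains share a global id; chains spanning fewer than `minExtent`
#' slices are removed. Per-slice partitions are preserved exactly — the
#' merge only relabels.
#'
#' @param slices list of label matrices, or an integer Z x H x W array.
#' @param linkIou linking threshold in \[0, 1\].
#' @param minExtent minimal number of slices a chain must span.
#' @return integer Z x H x W array with consistent ids across slices.
#' @export
mergeSliceSegmentations <- function(slices, linkIou = 0.5, minExtent = 1L) {
  if (is.array(slices) && length(dim(slices)) == 3L) {
    slices <- lapply(seq_len(dim(slices)[1L]), function(z) slices[z, , ])
  }
  Z <- length(slices)
  slices <- lapply(slices, relabelConsecutive)
  counts <- vapply(slices, function(s) length(objectIds(s)), integer(1))
  total <- sum(counts)
  offset <- cumsum(c(0L, counts))[seq_len(Z)]
  ## union-find over (slice, id) nodes
  parent <- seq_len(total)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (z in seq_len(Z - 1L)) {
    if (counts[z] == 0L || counts[z + 1L] == 0L) next
    pairs <- iouPairs(slices[[z]], slices[[z + 1L]])
    pairs <- pairs[pairs$iou > linkIou, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    pairs <- pairs[order(-pairs$iou, pairs$predId, pairs$gtId), ,
                   drop = FALSE]
    usedA <- logical(counts[z])
    usedB <- logical(counts[z + 1L])
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$predId[r]
      b <- pairs$gtId[r]
      if (usedA[a] || usedB[b]) next
      usedA[a] <- TRUE
      usedB[b] <- TRUE
      ra <- findRoot(offset[z] + a)
      rb <- findRoot(offset[z + 1L] + b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- if (total > 0L) vapply(seq_len(total), findRoot, integer(1))
           else integer()
  ## chain extents in slices
  nodeSlice <- rep(seq_len(Z), counts)
  extent <- integer(total)
  for (rt in unique(roots)) {
    extent[rt] <- length(unique(nodeSlice[roots == rt]))
  }
  keepRoot <- extent >= minExtent
  liveRoots <- unique(roots[keepRoot[roots]])
  idMap <- setNames(seq_along(liveRoots), liveRoots)
  out <- array(0L, dim = c(Z, dim(slices[[1L]])))
  for (z in seq_len(Z)) {
    lab <- slices[[z]]
    plane <- matrix(0L, nrow(lab), ncol(lab))
    for (a in seq_len(counts[z])) {
      rt <- roots[offset[z] + a]
      if (!keepRoot[rt]) next
      plane[lab == a] <- idMap[[as.character(rt)]]
    }
    out[z, , ] <- plane
  }
  out
}

#' Automatic volumetric segmentation (per-slice AIS or AMG + merge)
#'
#' Runs the chosen 2D automatic method on every slice and merges the
#' per-slice results with [mergeSliceSegmentations()].
#'
#' @param model a [PromptableModel-class] or per-slice list.
#' @param volume numeric Z x H x W array.
#' @param mode "ais" or "amg".
#' @param config an [aisConfig()] or [amgConfig()] matching `mode`.
#' @param linkIou,minExtent merge parameters.
#' @return integer Z x H x W label array.
#' @export
segmentVolumeAuto <- function(model, volume, mode = c("ais", "amg"),
                              config = NULL, linkIou = 0.5,
                              minExtent = 1L) {
  mode <- match.arg(mode)
  if (is.null(config)) {
    config <- if (mode == "ais") aisConfig() else amgConfig()
  }
  Z <- dim(volume)[1L]
  slices <- vector("list", Z)
  for (z in seq_len(Z)) {
    mz <- sliceModel(model, z)
    emb <- embedImage(mz, volume[z, , ])
    slices[[z]] <- if (mode == "ais") {
      aisSegment(aisPredict(mz, emb), config)
    } else {
      amgSegment(mz, emb, config)
    }
  }
  mergeSliceSegmentations(slices, linkIou = linkIou, minExtent = minExtent)
}

#' Track one object through a time series by mask projection
#'
#' Identical marching logic to [segmentObjectInVolume()], along time:
#' forward from the seed frame and optionally backward. The track ends
#' when the object disappears (empty prediction) or the frame-to-frame
#' IoU falls below `stopIou` (e.g. a jump larger than the object).
#'
#' @param model a [PromptableModel-class] or per-frame list.
#' @param frames numeric T x H x W array.
#' @param seedFrame frame carrying the seed prompts.
#' @param seedPrompts a [PromptSet-class].
#' @param stopIou stopping threshold.
#' @param backward also track backward from the seed frame.
#' @param addCentroidPoint include the previous centroid as a positive
#'   point.
#' @return list(labels = T x H x W integer array (track id 1), table =
#'   data.frame(track, frame, row, col, area)).
#' @export
trackObject <- function(model, frames, seedFrame, seedPrompts,
                        stopIou = 0.5, backward = FALSE,
                        addCentroidPoint = FALSE) {
  labels <- segmentObjectInVolume(model, frames, seedFrame, seedPrompts,
                                  stopIou = stopIou,
                                  addCentroidPoint = addCentroidPoint)
  if (!backward) {
    ## drop frames before the seed (forward-only tracking)
    if (seedFrame > 1L) labels[seq_len(seedFrame - 1L), , ] <- 0L
  }
  rows <- list()
  for (fr in seq_len(dim(frames)[1L])) {
    mask <- labels[fr, , ] > 0L
    if (!any(mask)) next
    w <- which(mask, arr.ind = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      track = 1L, frame = fr, row = mean(w[, 1L]), col = mean(w[, 2L]),
      area = nrow(w))
  }
  list(labels = labels,
       table = if (length(rows)) do.call(rbind, rows)
               else data.frame(track = integer(), frame = integer(),
                               row = numeric(), col = numeric(),
                               area = integer()))
}
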