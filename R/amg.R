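## amg: automatic mask generation — point-grid proposals through a
## promptable model, filtering by predicted IoU and stability score,
## non-maximum suppression, and threshold calibration.

#' Construct an AMG configuration
#'
#' Defaults follow common promptable-segmentation conventions; fine-tuned
#' models are typically better calibrated to microscopy and need lower
#' filtering thresholds, which is what [gridSearchAMG()] is for.
#'
#' @param pointsPerSide grid resolution; pointsPerSide^2 prompts per image.
#' @param iouThreshold minimum predicted IoU to keep a candidate.
#' @param stabilityThreshold minimum stability score to keep a candidate.
#' @param stabilityOffset logit offset delta of the stability score.
#' @param nmsIou suppression threshold for overlapping masks.
#' @param minObjectSize minimum candidate size in pixels.
#' @return an [AMGConfig-class].
#' @export
amgConfig <- function(pointsPerSide = 32L, iouThreshold = 0.88,
                      stabilityThreshold = 0.95, stabilityOffset = 1.0,
                      nmsIou = 0.7, minObjectSize = 10) {
  new("AMGConfig", pointsPerSide = as.integer(pointsPerSide),
      iouThreshold = iouThreshold, stabilityThreshold = stabilityThreshold,
      stabilityOffset = stabilityOffset, nmsIou = nmsIou,
      minObjectSize = minObjectSize)
}

#' Regular point grid covering an image
#'
#' `pointsPerSide` points per axis, evenly spaced with a half-cell offset
#' from the borders.
#'
#' @param shape integer (H, W).
#' @param pointsPerSide points per axis.
#' @return numeric matrix (pointsPerSide^2 x 2) of (row, col) coordinates.
#' @export
gridPoints <- function(shape, pointsPerSide) {
  if (pointsPerSide < 1L) stop("pointsPerSide must be >= 1")
  ## cell centers in 0-based continuous coordinates, shifted to 1-based
  ## pixel indices
  rs <- round((seq_len(pointsPerSide) - 0.5) / pointsPerSide * shape[1L]) + 1
  cs <- round((seq_len(pointsPerSide) - 0.5) / pointsPerSide * shape[2L]) + 1
  rs <- pmin(pmax(rs, 1), shape[1L])
  cs <- pmin(pmax(cs, 1), shape[2L])
  cbind(row = rep(rs, each = pointsPerSide), col = rep(cs, pointsPerSide))
}

#' Stability score of a logit map
#'
#' IoU between the masks obtained by thresholding the logits at +delta and
#' -delta; 1.0 when both are empty. Low values flag masks whose extent is
#' sensitive to the decision threshold.
#'
#' @param logits numeric matrix of mask logits.
#' @param delta non-negative logit offset.
#' @return numeric in \[0, 1\].
#' @export
stabilityScore <- function(logits, delta) {
  maskIoU(logits > delta, logits > -delta)
}

amgRawCandidates <- function(model, embedding, config) {
  pts <- gridPoints(embedding@shape, config@pointsPerSide)
  out <- list()
  for (i in seq_len(nrow(pts))) {
    prompts <- promptSet(points = matrix(pts[i, ], 1L, 2L), positive = TRUE)
    preds <- predictMasks(model, embedding, prompts, multimask = TRUE)
    for (p in preds) {
      mask <- p@logits > 0
      if (sum(mask) < config@minObjectSize) next
      out[[length(out) + 1L]] <- new("MaskCandidate", mask = mask,
        iouEstimate = p@iouEstimate,
        stability = stabilityScore(p@logits, config@stabilityOffset),
        sourcePoint = as.numeric(pts[i, ]))
    }
  }
  out
}

filterCandidates <- function(candidates, iouThreshold, stabilityThreshold) {
  Filter(function(cand) cand@iouEstimate >= iouThreshold &&
           cand@stability >= stabilityThreshold, candidates)
}

#' Generate filtered mask candidates from a point grid
#'
#' Predicts three candidate masks (multimask) for every grid point and
#' keeps those passing the predicted-IoU, stability and size filters.
#' Candidates carry their source point as provenance.
#'
#' @param model a [PromptableModel-class].
#' @param embedding an [ImageEmbedding-class] of the target image.
#' @param config an [amgConfig()].
#' @return list of [MaskCandidate-class].
#' @export
amgGenerate <- function(model, embedding, config = amgConfig()) {
  filterCandidates(amgRawCandidates(model, embedding, config),
                   config@iouThreshold, config@stabilityThreshold)
}

#' Greedy non-maximum suppression of mask candidates
#'
#' Candidates are visited by descending predicted IoU; a candidate is kept
#' iff its IoU with every already-kept mask is at most `nmsIou`. The kept
#' set is therefore an antichain under mask overlap.
#'
#' @param candidates list of [MaskCandidate-class].
#' @param nmsIou suppression threshold.
#' @return the kept subset, sorted by descending predicted IoU.
#' @export
nmsMasks <- function(candidates, nmsIou) {
  if (length(candidates) == 0L) return(candidates)
  ord <- order(vapply(candidates, function(cand) cand@iouEstimate,
                      numeric(1)), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    cand <- candidates[[i]]
    clash <- any(vapply(kept, function(k) maskIoU(k@mask, cand@mask) > nmsIou,
                        logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- cand
  }
  kept
}

#' Render kept candidates into a label image
#'
#' Masks are painted in ascending score order so that higher-scoring masks
#' overwrite residual overlaps; ids are 1..K.
#'
#' @param candidates list of [MaskCandidate-class] (typically after NMS).
#' @param shape integer (H, W) of the output.
#' @return integer label matrix.
#' @export
candidatesToLabels <- function(candidates, shape) {
  out <- matrix(0L, shape[1L], shape[2L])
  if (length(candidates) == 0L) return(out)
  ord <- order(vapply(candidates, function(cand) cand@iouEstimate,
                      numeric(1)))
  id <- 0L
  for (i in ord) {
    id <- id + 1L
    out[candidates[[i]]@mask] <- id
  }
  relabelConsecutive(out)
}

#' Run the full AMG pipeline on one image
#'
#' Proposal generation, filtering, NMS and label rendering.
#' @inheritParams amgGenerate
#' @return integer label matrix.
#' @export
amgSegment <- function(model, embedding, config = amgConfig()) {
  kept <- nmsMasks(amgGenerate(model, embedding, config), config@nmsIou)
  candidatesToLabels(kept, embedding@shape)
}

#' Calibrate AMG filtering thresholds by grid search
#'
#' Raw candidates are predicted once per validation image; every
#' (iouThreshold, stabilityThreshold) pair is then evaluated by filtering,
#' NMS, label rendering and mean mSA. Returns the argmax configuration
#' (first-in-grid on ties) and the full score table.
#'
#' @param model a [PromptableModel-class].
#' @param images list of validation images.
#' @param gts list of label matrices, parallel to `images`.
#' @param iouGrid,stabilityGrid thresholds to sweep.
#' @param base an [amgConfig()] providing the non-swept parameters.
#' @return list(config = best [AMGConfig-class], table = data.frame).
#' @export
gridSearchAMG <- function(model, images, gts,
                          iouGrid = seq(0.5, 0.9, by = 0.2),
                          stabilityGrid = seq(0.5, 0.9, by = 0.2),
                          base = amgConfig()) {
  stopifnot(length(images) == length(gts), length(images) > 0L)
  raw <- lapply(images, function(img) {
    emb <- embedImage(model, img)
    list(emb = emb, candidates = amgRawCandidates(model, emb, base))
  })
  grid <- expand.grid(iou = iouGrid, stability = stabilityGrid,
                      KEEP.OUT.ATTRS = FALSE)
  score <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    msas <- mapply(function(rc, gt) {
      kept <- nmsMasks(filterCandidates(rc$candidates, grid$iou[i],
                                        grid$stability[i]), base@nmsIou)
      meanSegmentationAccuracy(candidatesToLabels(kept, rc$emb@shape), gt)
    }, raw, gts)
    score[i] <- mean(msas)
  }
  grid$meanMSA <- score
  best <- which.max(score)
  bestCfg <- amgConfig(base@pointsPerSide, grid$iou[best],
                       grid$stability[best], base@stabilityOffset,
                       base@nmsIou, base@minObjectSize)
  list(config = bestCfg, table = grid)
}
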