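## ais: automatic instance segmentation via foreground / center-distance /
## boundary-distance channels, decoded with a seeded watershed, plus
## threshold calibration by grid search.

#' Construct an AIS decoding configuration
#'
#' @param centerThreshold,boundaryThreshold seed thresholds: seeds are
#'   connected components of (center < centerThreshold) &
#'   (boundary > boundaryThreshold).
#' @param foregroundThreshold mask threshold on the foreground channel.
#' @param minObjectSize minimum instance size in pixels.
#' @param heightmap watershed heightmap composition: "boundary"
#'   (1 - boundary distance; boundaries are ridges) or "combined"
#'   (0.5 * (center + 1 - boundary)).
#' @return an [AISConfig-class].
#' @export
aisConfig <- function(centerThreshold = 0.5, boundaryThreshold = 0.5,
                      foregroundThreshold = 0.5, minObjectSize = 10,
                      heightmap = "boundary") {
  new("AISConfig", centerThreshold = centerThreshold,
      boundaryThreshold = boundaryThreshold,
      foregroundThreshold = foregroundThreshold,
      minObjectSize = minObjectSize, heightmap = heightmap)
}

## Euclidean distance of every TRUE pixel to the nearest FALSE pixel;
## the image border counts as background (the mask is padded before the
## transform) so objects touching the border still get finite distances.
edtToBackground <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  padded <- matrix(0, H + 2L, W + 2L)
  padded[2:(H + 1L), 2:(W + 1L)] <- as.numeric(mask)
  d <- EBImage::imageData(EBImage::distmap(padded, metric = "euclidean"))
  d[2:(H + 1L), 2:(W + 1L)]
}

#' Compute the three AIS target channels from a label image
#'
#' Foreground is 1 on labeled pixels. Per object, the center distance is
#' the Euclidean distance to the object centroid divided by its per-object
#' maximum (0 at the center); if the centroid of a non-convex object falls
#' outside it, the pixel of maximal boundary distance serves as center.
#' The boundary distance is the Euclidean distance to the nearest
#' non-object pixel divided by its per-object maximum (1 at the innermost
#' pixel); a single-pixel object gets boundary distance 1. Background:
#' center = 1, boundary = 0.
#'
#' @param labels integer label matrix.
#' @return a [DistanceTargets-class].
#' @export
computeDistanceTargets <- function(labels) {
  assertLabels(labels)
  H <- nrow(labels)
  W <- ncol(labels)
  fg <- matrix(as.numeric(labels > 0), H, W)
  center <- matrix(1, H, W)
  boundary <- matrix(0, H, W)
  rows <- row(labels)
  cols <- col(labels)
  for (id in objectIds(labels)) {
    sel <- labels == id
    bd <- edtToBackground(sel)
    bmax <- max(bd[sel])
    boundary[sel] <- if (bmax > 0) bd[sel] / bmax else 1
    r <- rows[sel]
    c0 <- cols[sel]
    cr <- mean(r)
    cc <- mean(c0)
    ## centroid outside a non-convex object: recenter on the innermost pixel
    ri <- round(cr)
    ci <- round(cc)
    inObj <- ri >= 1 && ri <= H && ci >= 1 && ci <= W && labels[ri, ci] == id
    if (!inObj) {
      k <- which.max(bd[sel])
      cr <- r[k]
      cc <- c0[k]
    }
    cd <- sqrt((r - cr)^2 + (c0 - cc)^2)
    cmax <- max(cd)
    center[sel] <- if (cmax > 0) cd / cmax else 0
  }
  new("DistanceTargets", foreground = fg, center = center,
      boundary = boundary)
}

connectedComponents <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- EBImage::imageData(EBImage::bwlabel(m))
  storage.mode(out) <- "integer"
  out
}

#' Decode AIS channels into an instance segmentation
#'
#' Seeds are the connected components of pixels with center distance below
#' `centerThreshold` and boundary distance above `boundaryThreshold`; the
#' mask is the thresholded foreground; a seeded watershed over the distance
#' heightmap partitions the mask among the seeds. Instances smaller than
#' `minObjectSize` are removed and ids compacted. No seeds yields an empty
#' segmentation.
#'
#' @param channels a [DistanceTargets-class] (predicted or ideal).
#' @param config an [aisConfig()].
#' @return integer label matrix.
#' @export
aisSegment <- function(channels, config = aisConfig()) {
  stopifnot(is(channels, "DistanceTargets"))
  seedMask <- channels@center < config@centerThreshold &
    channels@boundary > config@boundaryThreshold
  mask <- channels@foreground > config@foregroundThreshold
  if (!any(mask) || !any(seedMask & mask)) {
    return(matrix(0L, nrow(channels@foreground), ncol(channels@foreground)))
  }
  seeds <- connectedComponents(seedMask)
  height <- switch(config@heightmap,
    boundary = 1 - channels@boundary,
    combined = 0.5 * (channels@center + 1 - channels@boundary))
  out <- .watershed_flood(height, seeds, mask)
  if (config@minObjectSize > 0) {
    sizes <- table(out[out > 0L])
    drop <- as.integer(names(sizes)[sizes < config@minObjectSize])
    if (length(drop)) out[out %in% drop] <- 0L
  }
  relabelConsecutive(out)
}

#' Calibrate AIS thresholds by grid search
#'
#' Decodes cached channel predictions for every grid point and scores the
#' mean mSA against validation ground truth; returns the argmax
#' configuration (ties broken by first-in-grid order) and the full score
#' table. Channels are computed once by the caller; only thresholds are
#' swept.
#'
#' @param predictions list of [DistanceTargets-class], one per validation
#'   image.
#' @param gts list of label matrices, parallel to `predictions`.
#' @param centerGrid,boundaryGrid,foregroundGrid numeric vectors of
#'   thresholds to sweep.
#' @param base an [aisConfig()] providing the non-swept parameters.
#' @return list(config = best [AISConfig-class], table = data.frame with
#'   one row per grid point and its mean mSA).
#' @export
gridSearchAIS <- function(predictions, gts,
                          centerGrid = seq(0.3, 0.7, by = 0.2),
                          boundaryGrid = seq(0.3, 0.7, by = 0.2),
                          foregroundGrid = 0.5,
                          base = aisConfig()) {
  stopifnot(length(predictions) == length(gts), length(predictions) > 0L)
  grid <- expand.grid(center = centerGrid, boundary = boundaryGrid,
                      foreground = foregroundGrid,
                      KEEP.OUT.ATTRS = FALSE)
  score <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- aisConfig(grid$center[i], grid$boundary[i], grid$foreground[i],
                     base@minObjectSize, base@heightmap)
    msas <- mapply(function(ch, gt) {
      meanSegmentationAccuracy(aisSegment(ch, cfg), gt)
    }, predictions, gts)
    score[i] <- mean(msas)
  }
  grid$meanMSA <- score
  best <- which.max(score)  # first maximum wins
  bestCfg <- aisConfig(grid$center[best], grid$boundary[best],
                       grid$foreground[best], base@minObjectSize,
                       base@heightmap)
  list(config = bestCfg, table = grid)
}
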