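# Fixtures are built in code: small disks/squares and the synthetic
# generator. No files are shipped.

diskMask <- function(H, W, cr, cc, r) {
  (row(matrix(0, H, W)) - cr)^2 + (col(matrix(0, H, W)) - cc)^2 <= r^2
}

labelsFromMasks <- function(masks) {
  out <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) out[masks[[i]]] <- i
  out
}

# two touching half-plane squares: ids 1 and 2 share a 1-px interface
touchingSquares <- function(H = 20L, W = 20L) {
  lab <- matrix(0L, H, W)
  lab[5:16, 4:10] <- 1L
  lab[5:16, 11:17] <- 2L
  lab
}

# small random label images for matcher fuzzing: up to `maxObj` rectangles
# that may overlap earlier ones (later ids overwrite)
randomLabels <- function(H = 24L, W = 24L, maxObj = 5L) {
  lab <- matrix(0L, H, W)
  n <- sample.int(maxObj + 1L, 1L) - 1L
  for (i in seq_len(n)) {
    h <- sample(3:9, 1L)
    w <- sample(3:9, 1L)
    r0 <- sample.int(H - h, 1L)
    c0 <- sample.int(W - w, 1L)
    lab[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- i
  }
  lab
}

# Brute-force instance matching: enumerate every one-to-one assignment of
# predictions to ground-truth objects over pairs with IoU > t and maximize
# total IoU. Independent of the package matcher.
bruteForceMatch <- function(pred, gt, t) {
  predIds <- objectIds(pred)
  gtIds <- objectIds(gt)
  iouOf <- function(p, g) maskIoU(pred == p, gt == g)
  iouTab <- outer(predIds, gtIds, Vectorize(iouOf))
  best <- list(total = 0, tp = 0L)
  recurse <- function(i, usedG, total, tp) {
    if (i > length(predIds)) {
      if (total > best$total + 1e-12 ||
          (abs(total - best$total) <= 1e-12 && tp > best$tp)) {
        best <<- list(total = total, tp = tp)
      }
      return(invisible(NULL))
    }
    recurse(i + 1L, usedG, total, tp)  # leave pred i unmatched
    for (j in seq_along(gtIds)) {
      if (!usedG[j] && iouTab[i, j] > t) {
        usedG[j] <- TRUE
        recurse(i + 1L, usedG, total + iouTab[i, j], tp + 1L)
        usedG[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(gtIds)), 0, 0L)
  list(tp = best$tp, fp = length(predIds) - best$tp,
       fn = length(gtIds) - best$tp, total = best$total)
}

withr_like_tempdir <- function() {
  d <- tempfile("pseg")
  dir.create(d)
  d
}

# default small-blob spec used across tests
testBlobSpec <- function(seed, nObjects = 5L, shape = c(64L, 64L),
                         touchingFraction = 0.2) {
  syntheticSpec(shape = shape, nObjects = nObjects, radiusRange = c(5, 8),
                touchingFraction = touchingFraction, seed = seed)
}
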