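## prompting: derive initial prompts from ground truth and correction
## prompts from prediction errors. Shared by training and the simulated
## interactive evaluation protocol.

#' Construct a PromptSet
#'
#' @param points numeric matrix (n x 2) of (row, col) coordinates (1-based),
#'   or NULL.
#' @param positive logical vector marking positive points (recycled if
#'   length 1).
#' @param box numeric c(minRow, minCol, maxRow, maxCol), inclusive, or NULL.
#' @param maskPrompt low-resolution logit matrix, or NULL.
#' @return a [PromptSet-class].
#' @export
promptSet <- function(points = NULL, positive = TRUE, box = NULL,
                      maskPrompt = NULL) {
  if (is.null(points)) {
    points <- matrix(numeric(), 0L, 2L)
    positive <- logical()
  } else {
    if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
    positive <- rep_len(positive, nrow(points))
  }
  new("PromptSet", points = points, positive = positive,
      box = if (is.null(box)) numeric() else as.numeric(box),
      maskPrompt = if (is.null(maskPrompt)) matrix(numeric(), 0L, 0L)
                   else maskPrompt)
}

#' @describeIn promptSet number of points in the set.
#' @param x a PromptSet.
#' @export
nPoints <- function(x) nrow(x@points)

#' @describeIn promptSet TRUE if the set carries a box.
#' @export
hasBox <- function(x) length(x@box) == 4L

#' @describeIn promptSet TRUE if the set carries a mask prompt.
#' @export
hasMaskPrompt <- function(x) length(x@maskPrompt) > 0L

setMethod("show", "PromptSet", function(object) {
  cat("PromptSet:", sum(object@positive), "positive /",
      sum(!object@positive), "negative point(s),",
      if (hasBox(object)) "box," else "no box,",
      if (hasMaskPrompt(object)) "mask prompt\n" else "no mask prompt\n")
})

#' Tight bounding box of a binary mask
#'
#' @param mask logical matrix with at least one TRUE pixel.
#' @return numeric c(minRow, minCol, maxRow, maxCol), inclusive.
#' @export
boxFromMask <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("cannot derive a box from an empty mask")
  c(min(w[, 1L]), min(w[, 2L]), max(w[, 1L]), max(w[, 2L]))
}

## Uniformly sample one pixel (row, col) from a logical mask.
samplePixel <- function(mask) {
  w <- which(mask)
  i <- if (length(w) == 1L) w else w[sample.int(length(w), 1L)]
  d <- dim(mask)
  r <- ((i - 1L) %% d[1L]) + 1L
  c((r), ((i - 1L) %/% d[1L]) + 1L)
}

#' Sample a random positive point inside a mask
#'
#' Uniform over the TRUE pixels; deterministic under `seed`.
#' @param mask logical matrix with at least one TRUE pixel.
#' @param seed optional integer seed.
#' @return numeric (row, col).
#' @export
samplePointInMask <- function(mask, seed = NULL) {
  if (!any(mask)) stop("cannot sample a point from an empty mask")
  withSeed(seed, samplePixel(mask))
}

#' Sample the initial prompt for one object
#'
#' Either a single positive point uniform over the object or its bounding
#' box — the two starting modes of interactive annotation.
#'
#' @param gtMask logical matrix of the target object.
#' @param mode "point" or "box".
#' @param seed optional integer seed.
#' @return a [PromptSet-class] with exactly one point or one box.
#' @export
sampleInitialPrompt <- function(gtMask, mode = c("point", "box"),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (!any(gtMask)) stop("cannot prompt an empty object")
  if (mode == "box") {
    promptSet(box = boxFromMask(gtMask))
  } else {
    promptSet(points = matrix(samplePointInMask(gtMask, seed), 1L, 2L),
              positive = TRUE)
  }
}

#' Sample a correction point pair from prediction errors
#'
#' The positive point is uniform over the missed area (gt minus prediction);
#' if the prediction covers the object completely, it falls back to a random
#' point inside the object. The negative point is uniform over the spurious
#' area (prediction minus gt); if there is none, it falls back to a random
#' point outside the object.
#'
#' @param gtMask logical matrix of the true object (nonempty).
#' @param predMask logical matrix of the current prediction.
#' @param seed optional integer seed.
#' @return list(positive = c(row, col), negative = c(row, col)).
#' @export
sampleCorrectionPoints <- function(gtMask, predMask, seed = NULL) {
  if (!identical(dim(gtMask), dim(predMask))) stop("mask shapes differ")
  if (!any(gtMask)) stop("cannot correct an empty object")
  withSeed(seed, {
    missed <- gtMask & !predMask
    spurious <- predMask & !gtMask
    pos <- samplePixel(if (any(missed)) missed else gtMask)
    negRegion <- if (any(spurious)) spurious else !gtMask
    if (!any(negRegion)) stop("no background pixel available")
    neg <- samplePixel(negRegion)
    list(positive = pos, negative = neg)
  })
}

#' Accumulate prompts across correction iterations
#'
#' New points are appended in order, the box (if any) is preserved, and the
#' mask prompt is replaced when a new one is provided.
#'
#' @param previous a [PromptSet-class].
#' @param newPoints numeric matrix (n x 2) of points to append, or NULL.
#' @param positive logical vector for `newPoints`.
#' @param maskPrompt replacement low-resolution logit map, or NULL to keep
#'   the previous one (absent stays absent).
#' @return the combined [PromptSet-class].
#' @export
accumulatePrompts <- function(previous, newPoints = NULL, positive = TRUE,
                              maskPrompt = NULL) {
  pts <- previous@points
  pos <- previous@positive
  if (!is.null(newPoints)) {
    if (is.null(dim(newPoints)))
      newPoints <- matrix(newPoints, ncol = 2L, byrow = TRUE)
    pts <- rbind(pts, newPoints)
    pos <- c(pos, rep_len(positive, nrow(newPoints)))
  }
  new("PromptSet", points = pts, positive = pos, box = previous@box,
      maskPrompt = if (is.null(maskPrompt)) previous@maskPrompt
                   else maskPrompt)
}
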