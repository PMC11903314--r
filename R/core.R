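## core: shared domain helpers, channel preparation and image/label I/O.
## Images are numeric matrices (H x W) or arrays (H x W x C, C <= 3);
## label images are non-negative integer matrices (0 = background); stacks
## and volumes are Z/T x H x W arrays.

#' Run an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded operations do not
#' perturb the caller's random stream.
#' @param seed integer seed or NULL (use the current stream unchanged).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

nChannels <- function(image) {
  if (is.matrix(image)) 1L else dim(image)[3L]
}

imageShape <- function(image) {
  d <- dim(image)
  as.integer(d[1:2])
}

#' Prepare an image for a three-channel encoder
#'
#' Single-channel images are replicated three times, two-channel images are
#' averaged per pixel and the mean replicated, three-channel images pass
#' through unchanged. More than three channels is an error.
#'
#' @param image numeric matrix (H x W) or array (H x W x C) with C in 1..3.
#' @return numeric array (H x W x 3).
#' @examples
#' x <- matrix(5, 4, 4)
#' dim(prepareImageChannels(x))  # 4 4 3
#' @export
prepareImageChannels <- function(image) {
  if (!is.numeric(image)) stop("image must be numeric")
  if (any(!is.finite(image))) stop("image must contain finite values")
  C <- nChannels(image)
  if (C > 3L) stop("images with more than 3 channels are not supported")
  if (C == 3L) return(image)
  mono <- if (C == 1L) {
    if (is.matrix(image)) image else image[, , 1L]
  } else {
    (image[, , 1L] + image[, , 2L]) / 2
  }
  array(mono, dim = c(dim(mono), 3L))
}

#' Min-max normalize image intensities to \[0, 1\]
#'
#' Applied per image before model input; constant images map to zero.
#' @param image numeric matrix or array.
#' @return object of the same shape with values in \[0, 1\].
#' @export
normalizeIntensity <- function(image) {
  r <- range(image)
  if (r[2] > r[1]) (image - r[1]) / (r[2] - r[1]) else image * 0
}

assertLabels <- function(labels) {
  if (!is.numeric(labels)) stop("labels must be numeric")
  if (any(labels < 0)) stop("labels must be non-negative")
  if (any(labels != round(labels))) stop("labels must be integer-valued")
  invisible(labels)
}

#' Ids of the objects present in a label image
#' @param labels label matrix/array (0 = background).
#' @return sorted integer vector of positive ids.
#' @export
objectIds <- function(labels) {
  ids <- sort(unique(as.integer(labels)))
  ids[ids > 0L]
}

#' Remap positive label ids to 1..K
#'
#' Background stays 0 and the per-pixel partition is unchanged; only the id
#' values are compacted (preserving their order).
#' @param labels label matrix/array.
#' @return relabeled object of the same shape, integer storage.
#' @export
relabelConsecutive <- function(labels) {
  assertLabels(labels)
  ids <- objectIds(labels)
  out <- array(0L, dim = if (is.null(dim(labels))) length(labels)
               else dim(labels))
  if (length(ids)) {
    map <- integer(max(ids))
    map[ids] <- seq_along(ids)
    pos <- labels > 0L
    out[pos] <- map[as.integer(labels[pos])]
  }
  if (is.matrix(labels) || length(dim(labels)) > 1L) out else as.integer(out)
}

## ---- I/O -------------------------------------------------------------

isTiffPath <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)
isPngPath <- function(path) grepl("\\.png$", path, ignore.case = TRUE)

checkReadable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  invisible(path)
}

#' Read an image from TIFF or PNG
#'
#' Single-plane files return a matrix (or an H x W x C array for
#' multi-channel PNG data); multi-plane TIFF stacks return a Z x H x W
#' array. The package's TIFF convention: samples of at most 16 bits are
#' integer data and return on their native integer scale; 32-bit samples
#' (and genuine floating-point TIFFs) are unit-interval intensities and
#' return as doubles.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @return numeric matrix or array.
#' @export
readImageFile <- function(path) {
  checkReadable(path)
  if (isPngPath(path)) {
    x <- png::readPNG(path)
    return(unclass(x))
  }
  if (!isTiffPath(path)) stop("unsupported image format: ", path)
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (!is.null(info$bits.per.sample)) info <- list(info)  # single plane
  bits <- max(unlist(lapply(info, `[[`, "bits.per.sample")))
  asInt <- bits <= 16L
  planes <- tiff::readTIFF(path, all = TRUE, as.is = asInt)
  planes <- lapply(planes, function(p) {
    storage.mode(p) <- "double"
    p
  })
  if (length(planes) == 1L) return(planes[[1L]])
  d <- dim(planes[[1L]])
  if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1))))
    stop("stack planes have inconsistent shapes")
  out <- array(0, dim = c(length(planes), d))
  for (z in seq_along(planes)) out[z, , ] <- planes[[z]]
  out
}

#' Write an image to TIFF or PNG
#'
#' Non-negative integer data up to 65535 round-trips exactly (16-bit
#' unsigned samples); fractional data must lie in \[0, 1\] and round-trips
#' at 32-bit precision. A Z x H x W array is written as a multi-plane TIFF
#' stack.
#'
#' @param path destination path.
#' @param image numeric matrix or array.
#' @return `path`, invisibly.
#' @export
writeImageFile <- function(path, image) {
  if (!is.numeric(image)) stop("image must be numeric")
  if (any(!is.finite(image))) stop("image must contain finite values")
  isInt <- all(image == round(image)) && min(image) >= 0
  if (isInt && max(image) > 65535)
    stop("integer data above 65535 is not supported; rescale to [0, 1]")
  if (!isInt && (min(image) < 0 || max(image) > 1))
    stop("fractional data must lie in [0, 1]")
  if (isPngPath(path)) {
    if (length(dim(image)) == 3L && dim(image)[3L] > 4L)
      stop("PNG supports at most 4 channels")
    if (isInt) {
      bits <- if (max(image) > 255) 16 else 8
      png::writePNG(image / (2^bits - 1), path)
    } else {
      png::writePNG(image, path)
    }
    return(invisible(path))
  }
  if (!isTiffPath(path)) stop("unsupported image format: ", path)
  scale <- if (isInt) 65535 else 1
  bits <- if (isInt) 16L else 32L
  if (length(dim(image)) == 3L) {
    ## 3D arrays are written as Z x H x W multi-plane stacks
    planes <- lapply(seq_len(dim(image)[1L]), function(z) image[z, , ] / scale)
    tiff::writeTIFF(planes, path, bits.per.sample = bits)
  } else {
    tiff::writeTIFF(image / scale, path, bits.per.sample = bits)
  }
  invisible(path)
}

#' Read a label image (integer TIFF)
#'
#' @param path TIFF file with non-negative integer samples; float-typed
#'   files are rejected.
#' @return integer label matrix (or Z x H x W array for stacks).
#' @export
readLabels <- function(path) {
  checkReadable(path)
  x <- readImageFile(path)
  if (any(x != round(x)))
    stop("label file is float-typed (non-integer values): ", path)
  if (any(x < 0)) stop("label file contains negative values: ", path)
  storage.mode(x) <- "integer"
  x
}

#' Write a label image as integer TIFF
#'
#' @param path destination path (.tif/.tiff).
#' @param labels non-negative integer matrix or Z x H x W array.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(path, labels) {
  assertLabels(labels)
  if (!isTiffPath(path)) stop("labels must be written as TIFF")
  writeImageFile(path, labels)
}
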