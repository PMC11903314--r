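## synthetic: deterministic generator of microscopy-like blob images with
## ground-truth labels (2D, volumes, time series). Emulates fluorescence
## nucleus/cell imagery: bright elliptical objects on a dark background
## with additive Gaussian noise, optionally touching but never overlapping.

#' Construct a synthetic-data specification
#'
#' The spec fully determines the output: identical specs (including the
#' seed) generate identical arrays.
#'
#' @param shape integer (H, W) for 2D, (Z, H, W) for volumes, (T, H, W)
#'   for time series.
#' @param nObjects number of objects (>= 0).
#' @param radiusRange min/max object radius in pixels (>= 2).
#' @param touchingFraction fraction of objects placed adjacent to an
#'   earlier object — sharing a boundary without overlapping (2D only).
#' @param fgIntensity,bgIntensity noise-free object and background
#'   intensities (unit scale).
#' @param noiseSigma standard deviation of additive Gaussian noise.
#' @param driftPerFrame maximal per-axis displacement per frame (time
#'   series only).
#' @param seed integer RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(shape = c(128L, 128L), nObjects = 10L,
                          radiusRange = c(6, 10), touchingFraction = 0.2,
                          fgIntensity = 0.8, bgIntensity = 0.2,
                          noiseSigma = 0.05, driftPerFrame = 2,
                          seed = 1L) {
  new("SyntheticSpec", shape = as.integer(shape),
      nObjects = as.integer(nObjects), radiusRange = as.numeric(radiusRange),
      touchingFraction = touchingFraction, fgIntensity = fgIntensity,
      bgIntensity = bgIntensity, noiseSigma = noiseSigma,
      driftPerFrame = driftPerFrame, seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", paste(object@shape, collapse = " x "), "|",
      object@nObjects, "objects, radii",
      paste(object@radiusRange, collapse = "-"), "px, seed",
      object@seed, "\n")
})

## logical mask of an ellipse (rotation theta, semi-axes a/b) on an
## H x W grid
ellipseMask <- function(H, W, cr, cc, a, b, theta) {
  dr <- row(matrix(0, H, W)) - cr
  dc <- col(matrix(0, H, W)) - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

## 4-neighborhood binary dilation (used for adjacency / gap tests)
dilate4 <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  out <- mask
  out[-1, ] <- out[-1, ] | mask[-H, ]
  out[-H, ] <- out[-H, ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -W]
  out[, -W] <- out[, -W] | mask[, -1]
  out
}

renderBlobs <- function(labels, spec) {
  img <- matrix(spec@bgIntensity, nrow(labels), ncol(labels))
  img[labels > 0L] <- spec@fgIntensity
  if (spec@noiseSigma > 0) {
    img <- img + matrix(rnorm(length(img), sd = spec@noiseSigma),
                        nrow(labels), ncol(labels))
  }
  img
}

#' Generate a 2D blob image with ground-truth labels
#'
#' Elliptical objects with random radii (within `radiusRange`) and
#' orientation; a `touchingFraction` of objects is placed adjacent to an
#' earlier object (masks share a 4-neighborhood boundary but never
#' overlap), the rest keep at least a one-pixel gap. Placement that cannot
#' satisfy the constraints within a bounded number of retries raises an
#' infeasible-packing error.
#'
#' @param spec a [syntheticSpec()] with a 2D shape.
#' @return list(image = numeric matrix, labels = integer matrix).
#' @export
generateBlobs2D <- function(spec) {
  if (length(spec@shape) != 2L) stop("generateBlobs2D needs a 2D shape")
  withSeed(spec@seed, {
    H <- spec@shape[1L]
    W <- spec@shape[2L]
    labels <- matrix(0L, H, W)
    if (spec@nObjects > 0L) {
      nTouch <- round(spec@touchingFraction * spec@nObjects)
      touchFlags <- rep(FALSE, spec@nObjects)
      if (nTouch > 0L && spec@nObjects > 1L) {
        touchFlags[sample(2:spec@nObjects, min(nTouch, spec@nObjects - 1L))] <-
          TRUE
      }
      for (i in seq_len(spec@nObjects)) {
        placed <- placeBlob(labels, spec, touching = touchFlags[i])
        if (is.null(placed)) {
          stop("infeasible packing: could not place object ", i,
               " without overlap")
        }
        labels[placed] <- i
      }
    }
    list(image = renderBlobs(labels, spec), labels = labels)
  })
}

## try to place one ellipse; returns its mask or NULL after bounded retries
placeBlob <- function(labels, spec, touching = FALSE, maxTries = 200L) {
  H <- nrow(labels)
  W <- ncol(labels)
  occ <- labels > 0L
  occGrown <- dilate4(occ)
  for (try in seq_len(maxTries)) {
    a <- runif(1, spec@radiusRange[1L], spec@radiusRange[2L])
    b <- runif(1, spec@radiusRange[1L], spec@radiusRange[2L])
    theta <- runif(1, 0, pi)
    rmax <- max(a, b)
    if (touching && any(occ)) {
      ## walk outward from a random existing object until disjoint
      anchor <- samplePixel(occ)
      phi <- runif(1, 0, 2 * pi)
      for (d in seq(1, 3 * rmax + 2, by = 1)) {
        cr <- round(anchor[1L] + d * cos(phi))
        cc <- round(anchor[2L] + d * sin(phi))
        if (cr < rmax + 1 || cr > H - rmax || cc < rmax + 1 ||
            cc > W - rmax) break
        m <- ellipseMask(H, W, cr, cc, a, b, theta)
        if (!any(m & occ)) {
          if (any(m & occGrown)) return(which(m))  # adjacent, not overlapping
          break                                    # walked past adjacency
        }
      }
    } else {
      cr <- runif(1, rmax + 1, H - rmax)
      cc <- runif(1, rmax + 1, W - rmax)
      m <- ellipseMask(H, W, cr, cc, a, b, theta)
      if (!any(m & occGrown)) return(which(m))     # keeps a >= 1 px gap
    }
  }
  NULL
}

#' Generate a 3D volume of ellipsoidal blobs
#'
#' Ellipsoids span several z-slices with consistent per-slice
#' cross-sections; objects never overlap.
#'
#' @param spec a [syntheticSpec()] with shape (Z, H, W).
#' @return list(image = Z x H x W array, labels = Z x H x W integer array).
#' @export
generateVolume <- function(spec) {
  if (length(spec@shape) != 3L) stop("generateVolume needs a (Z, H, W) shape")
  withSeed(spec@seed, {
    Z <- spec@shape[1L]
    H <- spec@shape[2L]
    W <- spec@shape[3L]
    labels <- array(0L, dim = c(Z, H, W))
    centers <- matrix(numeric(), 0L, 4L)  # cz, cr, cc, rmax
    for (i in seq_len(spec@nObjects)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        rz <- runif(1, spec@radiusRange[1L], spec@radiusRange[2L])
        rr <- runif(1, spec@radiusRange[1L], spec@radiusRange[2L])
        rc <- runif(1, spec@radiusRange[1L], spec@radiusRange[2L])
        if (diff(spec@radiusRange) == 0) rz <- rr <- rc  # exact spheres
        rmax <- max(rz, rr, rc)
        ## integer centers: a radius-r sphere then spans exactly 2r + 1
        ## slices (the pole slices contain the center pixel)
        cz <- if (Z > 2 * rmax + 1) round(runif(1, rmax + 1, Z - rmax))
              else round((Z + 1) / 2)
        cr <- round(runif(1, rmax + 1, H - rmax))
        cc <- round(runif(1, rmax + 1, W - rmax))
        sep <- TRUE
        if (nrow(centers)) {
          d <- sqrt((centers[, 1L] - cz)^2 + (centers[, 2L] - cr)^2 +
                    (centers[, 3L] - cc)^2)
          sep <- all(d > centers[, 4L] + rmax + 2)
        }
        if (!sep) next
        for (z in seq_len(Z)) {
          t2 <- 1 - ((z - cz) / rz)^2
          if (t2 < 0) next
          sl <- ellipseMask(H, W, cr, cc, rr * sqrt(t2) + 1e-9,
                            rc * sqrt(t2) + 1e-9, 0)
          plane <- labels[z, , ]
          plane[sl] <- i
          labels[z, , ] <- plane
        }
        centers <- rbind(centers, c(cz, cr, cc, rmax))
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible packing: could not place ellipsoid ", i)
    }
    image <- array(spec@bgIntensity, dim = dim(labels))
    image[labels > 0L] <- spec@fgIntensity
    if (spec@noiseSigma > 0) {
      image <- image + array(rnorm(length(image), sd = spec@noiseSigma),
                             dim = dim(labels))
    }
    list(image = image, labels = labels)
  })
}

#' Generate a 2D time series with drifting objects
#'
#' Objects persist across frames with stable ids (ground-truth tracks);
#' each frame every object attempts an independent uniform per-axis step
#' in \[-drift, +drift\] and keeps its previous position when the step
#' would cause an overlap or leave the image.
#'
#' @param spec a [syntheticSpec()] with shape (T, H, W).
#' @return list(image = T x H x W array, labels = T x H x W integer array).
#' @export
generateTimeseries <- function(spec) {
  if (length(spec@shape) != 3L)
    stop("generateTimeseries needs a (T, H, W) shape")
  withSeed(spec@seed, {
    TT <- spec@shape[1L]
    H <- spec@shape[2L]
    W <- spec@shape[3L]
    ## initial placement (no touching: drifting objects need room)
    labels0 <- matrix(0L, H, W)
    params <- vector("list", spec@nObjects)
    for (i in seq_len(spec@nObjects)) {
      a <- runif(1, spec@radiusRange[1L], spec@radiusRange[2L])
      b <- runif(1, spec@radiusRange[1L], spec@radiusRange[2L])
      theta <- runif(1, 0, pi)
      rmax <- max(a, b)
      done <- FALSE
      for (try in seq_len(200L)) {
        cr <- runif(1, rmax + 1, H - rmax)
        cc <- runif(1, rmax + 1, W - rmax)
        m <- ellipseMask(H, W, cr, cc, a, b, theta)
        if (!any(m & dilate4(labels0 > 0L))) {
          labels0[m] <- i
          params[[i]] <- list(a = a, b = b, theta = theta, cr = cr, cc = cc,
                              rmax = rmax)
          done <- TRUE
          break
        }
      }
      if (!done) stop("infeasible packing: could not place object ", i)
    }
    labels <- array(0L, dim = c(TT, H, W))
    image <- array(0, dim = c(TT, H, W))
    for (fr in seq_len(TT)) {
      if (fr > 1L && spec@driftPerFrame > 0) {
        for (i in seq_len(spec@nObjects)) {
          p <- params[[i]]
          ## integer steps: the mask translates exactly, so the centroid
          ## displacement is bounded by driftPerFrame per axis
          dmax <- floor(spec@driftPerFrame)
          nr <- p$cr + sample(-dmax:dmax, 1L)
          nc <- p$cc + sample(-dmax:dmax, 1L)
          if (nr < p$rmax + 1 || nr > H - p$rmax || nc < p$rmax + 1 ||
              nc > W - p$rmax) next
          others <- matrix(FALSE, H, W)
          for (j in seq_len(spec@nObjects)) {
            if (j == i) next
            q <- params[[j]]
            others <- others | ellipseMask(H, W, q$cr, q$cc, q$a, q$b,
                                           q$theta)
          }
          m <- ellipseMask(H, W, nr, nc, p$a, p$b, p$theta)
          if (!any(m & dilate4(others))) {
            params[[i]]$cr <- nr
            params[[i]]$cc <- nc
          }
        }
      }
      lab <- matrix(0L, H, W)
      for (i in seq_len(spec@nObjects)) {
        p <- params[[i]]
        lab[ellipseMask(H, W, p$cr, p$cc, p$a, p$b, p$theta)] <- i
      }
      labels[fr, , ] <- lab
      image[fr, , ] <- renderBlobs(lab, spec)
    }
    list(image = image, labels = labels)
  })
}
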