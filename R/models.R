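## models: the promptable-model contract plus two reference
## implementations — a ground-truth-driven oracle (deterministic test
## double) and a small trainable convolutional model — and a persistent
## embedding cache.

#' Deterministic oracle model driven by ground truth
#'
#' The oracle answers prompts from a label image: it returns the object
#' containing the first positive point (or, for a box-only prompt, the
#' object with the largest overlap with the box), optionally dilated or
#' eroded by `k` pixels. Its IoU estimate is the true IoU of the returned
#' mask against the untransformed object. A negative point removes the
#' ground-truth object containing it from the output (the prediction
#' becomes empty if that is the target object itself); negative points on
#' background leave the mask unchanged. Used to anchor protocol tests.
#'
#' @param gt integer label matrix (0 = background).
#' @param behavior "exact", "dilate" or "erode".
#' @param k structuring-element radius for dilate/erode.
#' @return an [OracleModel][PromptableModel-class].
#' @export
oracleModel <- function(gt, behavior = c("exact", "dilate", "erode"),
                        k = 0L) {
  behavior <- match.arg(behavior)
  assertLabels(gt)
  if (behavior != "exact" && k < 1L) stop("dilate/erode require k >= 1")
  storage.mode(gt) <- "integer"
  new("OracleModel", labels = gt, behavior = behavior, k = as.integer(k))
}

discBrush <- function(k) EBImage::makeBrush(2L * k + 1L, shape = "disc")

morphMask <- function(mask, behavior, k) {
  if (behavior == "exact" || !any(mask)) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- if (behavior == "dilate") EBImage::dilate(m, discBrush(k))
         else EBImage::erode(m, discBrush(k))
  matrix(EBImage::imageData(out) > 0.5, nrow(mask), ncol(mask))
}

setMethod("embedImage", "OracleModel", function(model, image) {
  shape <- imageShape(prepareImageChannels(image))
  if (!identical(shape, dim(model@labels)))
    stop("image shape does not match the oracle's ground truth")
  new("ImageEmbedding", features = array(0, dim = c(1L, 1L, 1L)),
      scale = 1L, shape = as.integer(shape), extra = list())
})

oraclePredictOne <- function(model, prompts) {
  lab <- model@labels
  target <- 0L
  if (nPoints(prompts) > 0L && any(prompts@positive)) {
    p <- prompts@points[which(prompts@positive)[1L], ]
    target <- lab[p[1L], p[2L]]
  } else if (hasBox(prompts)) {
    b <- round(prompts@box)
    sub <- lab[b[1L]:b[3L], b[2L]:b[4L], drop = FALSE]
    ids <- objectIds(sub)
    if (length(ids)) {
      ov <- vapply(ids, function(i) sum(sub == i), numeric(1))
      target <- ids[which.max(ov)]
    }
  } else {
    stop("prompt set carries neither a point nor a box")
  }
  if (target == 0L) {
    mask <- matrix(FALSE, nrow(lab), ncol(lab))
    return(new("MaskPrediction", logits = ifelse(mask, 10, -10),
               iouEstimate = 0))
  }
  gtMask <- lab == target
  mask <- morphMask(gtMask, model@behavior, model@k)
  if (nPoints(prompts) > 0L && any(!prompts@positive)) {
    negs <- prompts@points[!prompts@positive, , drop = FALSE]
    negIds <- unique(lab[negs])
    negIds <- negIds[negIds > 0L]
    if (target %in% negIds) {
      mask <- mask & FALSE
    } else if (length(negIds)) {
      mask <- mask & !(lab %in% negIds)
    }
  }
  est <- if (any(mask)) maskIoU(mask, gtMask) else 0
  new("MaskPrediction", logits = ifelse(mask, 10, -10), iouEstimate = est)
}

setMethod("predictMasks", "OracleModel",
          function(model, embedding, prompts, multimask = FALSE) {
  pred <- oraclePredictOne(model, prompts)
  if (multimask) list(pred, pred, pred) else list(pred)
})

setMethod("aisPredict", "OracleModel", function(model, embedding) {
  computeDistanceTargets(model@labels)
})

setMethod("trainableGroups", "OracleModel", function(model) character())

setMethod("show", "OracleModel", function(object) {
  cat("OracleModel(", object@behavior,
      if (object@behavior != "exact") paste0("(k=", object@k, ")"), ") on ",
      paste(dim(object@labels), collapse = " x "), " ground truth\n",
      sep = "")
})

## ---- toy trainable model --------------------------------------------

#' Small trainable promptable model
#'
#' A desk-scale stand-in for a promptable segmentation network, mirroring
#' the encoder / prompt-encoder / mask-decoder decomposition: a two-layer
#' convolutional encoder downsamples the (three-channel, min-max
#' normalized) image by `scale`; prompts are rasterized into four channels
#' at embedding resolution (positive-point splat, negative-point splat, box
#' interior, squashed mask prompt); the mask decoder fuses both and emits
#' one single-mask logit map plus three multimask logit maps (bilinearly
#' upsampled to full resolution) with matching IoU estimates; a separate
#' AIS decoder head emits the three instance-segmentation channels.
#'
#' @param C1,D,P,Hc channel widths (first encoder layer, embedding, prompt
#'   features, decoder hidden layer).
#' @param scale spatial downsampling factor of the embedding.
#' @param promptSigma width (full-resolution pixels) of the point splats.
#' @param seed weight-initialization seed.
#' @return a [ToyPromptableModel][PromptableModel-class].
#' @export
toyPromptableModel <- function(C1 = 8L, D = 16L, P = 8L, Hc = 16L,
                               scale = 4L, promptSigma = 8, seed = 42L) {
  if (any(c(C1, D, P, Hc, scale) < 1L)) stop("channel counts must be >= 1")
  arch <- toyArch(C1, D, P, Hc, scale, promptSigma)
  new("ToyPromptableModel", arch = arch,
      weights = toyInitWeights(arch, seed))
}

nParameters <- function(model) {
  sum(vapply(ls(model@weights),
             function(nm) length(model@weights[[nm]]), numeric(1)))
}

setMethod("show", "ToyPromptableModel", function(object) {
  cat("ToyPromptableModel:", nParameters(object), "parameters, scale",
      object@arch$scale, "\n")
})

## pad the image (bottom/right, zeros) to a multiple of the encoder scale
padToScale <- function(x, s) {
  d <- dim(x)
  H2 <- ceiling(d[1L] / s) * s
  W2 <- ceiling(d[2L] / s) * s
  if (H2 == d[1L] && W2 == d[2L]) return(x)
  out <- array(0, dim = c(H2, W2, if (length(d) > 2L) d[3L] else NULL))
  if (length(d) > 2L) out[seq_len(d[1L]), seq_len(d[2L]), ] <- x
  else out[seq_len(d[1L]), seq_len(d[2L])] <- x
  out
}

toyEmbedInternal <- function(model, image) {
  x <- prepareImageChannels(image)
  shape <- imageShape(x)
  x <- normalizeIntensity(x)
  x <- padToScale(x, model@arch$scale)
  g <- geom(dim(x)[1L], dim(x)[2L], model@arch$scale)
  X0 <- matrix(x, g$H * g$W, 3L)
  cache <- encForward(model@weights, X0, g)
  list(cache = cache, g = g, X0 = X0, shape = shape)
}

setMethod("embedImage", "ToyPromptableModel", function(model, image) {
  fw <- toyEmbedInternal(model, image)
  new("ImageEmbedding",
      features = array(fw$cache$E, dim = c(fw$g$h, fw$g$w, model@arch$D)),
      scale = model@arch$scale, shape = fw$shape,
      extra = list(g = fw$g, E = fw$cache$E, H1 = fw$cache$H1))
})

toyDecode <- function(model, embedding, prompts) {
  g <- embedding@extra$g
  M <- rasterPrompts(prompts, g, model@arch$promptSigma)
  decForward(model@weights, embedding@extra$E, M, g, embedding@extra$H1)
}

cropLogits <- function(vec, g, shape) {
  matrix(vec, g$H, g$W)[seq_len(shape[1L]), seq_len(shape[2L]), drop = FALSE]
}

setMethod("predictMasks", "ToyPromptableModel",
          function(model, embedding, prompts, multimask = FALSE) {
  if (nPoints(prompts) == 0L && !hasBox(prompts))
    stop("prompt set carries neither a point nor a box")
  dec <- toyDecode(model, embedding, prompts)
  g <- embedding@extra$g
  chans <- if (multimask) 2:4 else 1L
  lapply(chans, function(k) {
    new("MaskPrediction",
        logits = cropLogits(dec$Lfull[, k], g, embedding@shape),
        iouEstimate = dec$iouEst[k])
  })
})

setMethod("aisPredict", "ToyPromptableModel", function(model, embedding) {
  g <- embedding@extra$g
  fw <- aisForward(model@weights, embedding@extra$E, g, embedding@extra$H1)
  shape <- embedding@shape
  new("DistanceTargets",
      foreground = cropLogits(fw$probs[, 1L], g, shape),
      center = cropLogits(fw$probs[, 2L], g, shape),
      boundary = cropLogits(fw$probs[, 3L], g, shape))
})

setMethod("trainableGroups", "ToyPromptableModel", function(model) {
  names(paramGroups)
})

## snapshot / restore weights (used for checkpointing and best-epoch
## restoration during training)
weightsAsList <- function(model) {
  nms <- ls(model@weights)
  setNames(lapply(nms, function(nm) model@weights[[nm]]), nms)
}

restoreWeights <- function(model, wlist) {
  for (nm in names(wlist)) model@weights[[nm]] <- wlist[[nm]]
  invisible(model)
}

#' Save / load a toy model checkpoint
#'
#' The checkpoint stores the architecture description and all weight
#' matrices; reloading reproduces predictions exactly.
#' @param model a [ToyPromptableModel][PromptableModel-class].
#' @param path destination file.
#' @return `path` (save) or the reloaded model (load).
#' @export
saveToyModel <- function(model, path) {
  saveRDS(list(arch = model@arch, weights = weightsAsList(model)), path)
  invisible(path)
}

#' @rdname saveToyModel
#' @export
loadToyModel <- function(path) {
  ck <- readRDS(path)
  m <- new("ToyPromptableModel", arch = ck$arch,
           weights = new.env(parent = emptyenv()))
  restoreWeights(m, ck$weights)
  m
}

## ---- embedding cache -------------------------------------------------

#' Persistent embedding cache
#'
#' Embeddings are expensive relative to decoding, and interactive use
#' recomputes masks for changing prompts on a fixed image; the cache
#' persists embeddings in a single RDS archive keyed by a caller-supplied
#' string (e.g. model id + image hash).
#'
#' @param storePath file path of the cache archive (created on first use).
#' @return an object usable with [getOrComputeEmbedding()].
#' @export
embeddingCache <- function(storePath) {
  structure(list(path = storePath), class = "EmbeddingCache")
}

readCacheStore <- function(cache) {
  if (!file.exists(cache$path)) return(list(entries = list(), misses = 0L))
  tryCatch(readRDS(cache$path), error = function(e) {
    warning("corrupt embedding cache; recomputing: ", conditionMessage(e))
    list(entries = list(), misses = 0L)
  })
}

#' Fetch an embedding from the cache or compute and persist it
#'
#' The first call for a key invokes the model encoder and stores the
#' result; later calls return the stored embedding bit-identically without
#' touching the model. A corrupt archive is recomputed with a warning.
#'
#' @param cache an [embeddingCache()].
#' @param model a [PromptableModel-class].
#' @param image the image to embed.
#' @param key unique string identifying (model, image).
#' @return an [ImageEmbedding-class].
#' @export
getOrComputeEmbedding <- function(cache, model, image, key) {
  store <- readCacheStore(cache)
  if (!is.null(store$entries[[key]])) return(store$entries[[key]])
  emb <- embedImage(model, image)
  store$entries[[key]] <- emb
  store$misses <- store$misses + 1L
  saveRDS(store, cache$path)
  emb
}

#' @describeIn getOrComputeEmbedding number of encoder invocations the
#'   cache has performed (cache misses) — observable evidence that hits do
#'   not re-invoke the encoder.
#' @export
cacheMisses <- function(cache) readCacheStore(cache)$misses
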