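#' @import methods
#' @importFrom stats rnorm runif setNames aggregate sd
#' @importFrom utils head tail
#' @useDynLib promptSeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Central value classes. Images and label images are deliberately plain R
## matrices/arrays (H x W [x C] and Z/T x H x W); the S4 layer covers the
## domain objects that carry structure: prompts, predictions, targets,
## configurations and models.

#' PromptSet: a set of user (or simulated) annotations for one object
#'
#' Points are stored as a two-column matrix of (row, col) pixel coordinates
#' (1-based, pixel-center semantics) with a parallel logical vector marking
#' positive points. The box, if present, is `c(minRow, minCol, maxRow,
#' maxCol)`, inclusive on both ends. The mask prompt, if present, is a
#' low-resolution logit map at the model's embedding resolution.
#'
#' @slot points numeric matrix (n x 2) of point coordinates.
#' @slot positive logical vector of length n; TRUE = positive point.
#' @slot box numeric of length 0 (absent) or 4.
#' @slot maskPrompt numeric matrix; 0 x 0 when absent.
#' @export
setClass("PromptSet", representation(
  points = "matrix", positive = "logical", box = "numeric",
  maskPrompt = "matrix"
), validity = function(object) {
  if (ncol(object@points) != 2 && nrow(object@points) > 0)
    return("points must have two columns (row, col)")
  if (nrow(object@points) != length(object@positive))
    return("positive must have one entry per point")
  if (!(length(object@box) %in% c(0L, 4L)))
    return("box must be absent or c(minRow, minCol, maxRow, maxCol)")
  if (length(object@box) == 4L &&
      (object@box[1] > object@box[3] || object@box[2] > object@box[4]))
    return("box min must not exceed max")
  TRUE
})

#' MaskPrediction: one predicted mask with its self-estimated quality
#'
#' @slot logits numeric matrix at full image resolution; thresholding at 0
#'   yields the binary mask.
#' @slot iouEstimate predicted IoU of that mask with the true object, in
#'   \[0, 1\].
#' @export
setClass("MaskPrediction", representation(
  logits = "matrix", iouEstimate = "numeric"
))

#' ImageEmbedding: prompt-independent features of one image
#'
#' @slot features numeric array (h x w x D) of spatially downsampled features.
#' @slot scale integer downsampling factor relative to the input.
#' @slot shape integer original image shape (H, W).
#' @slot extra list of model-specific payload (the oracle stores nothing; the
#'   toy model stores forward-pass caches here).
#' @export
setClass("ImageEmbedding", representation(
  features = "array", scale = "integer", shape = "integer", extra = "list"
))

#' DistanceTargets: the three AIS channels
#'
#' Foreground probability, normalized distance to the object center and
#' normalized distance to the object boundary; all in \[0, 1\] and sharing
#' the image shape. Background convention: center = 1, boundary = 0.
#'
#' @slot foreground,center,boundary numeric matrices in \[0, 1\].
#' @export
setClass("DistanceTargets", representation(
  foreground = "matrix", center = "matrix", boundary = "matrix"
), validity = function(object) {
  d <- dim(object@foreground)
  if (!identical(d, dim(object@center)) || !identical(d, dim(object@boundary)))
    return("all three channels must share the same shape")
  TRUE
})

#' MatchResult: instance matching at one IoU threshold
#'
#' @slot threshold the IoU threshold t.
#' @slot tp,fp,fn true positive / false positive / false negative counts.
#' @slot pairs data.frame with columns predId, gtId, iou (the matched pairs).
#' @export
setClass("MatchResult", representation(
  threshold = "numeric", tp = "integer", fp = "integer", fn = "integer",
  pairs = "data.frame"
))

#' MaskCandidate: one AMG proposal
#'
#' @slot mask logical matrix.
#' @slot iouEstimate,stability quality scores in \[0, 1\].
#' @slot sourcePoint numeric (row, col) of the generating grid point.
#' @export
setClass("MaskCandidate", representation(
  mask = "matrix", iouEstimate = "numeric", stability = "numeric",
  sourcePoint = "numeric"
))

#' AISConfig: decoding thresholds for automatic instance segmentation
#'
#' @slot centerThreshold seeds require center distance below this value.
#' @slot boundaryThreshold seeds require boundary distance above this value.
#' @slot foregroundThreshold mask = foreground probability above this value.
#' @slot minObjectSize instances smaller than this many pixels are removed.
#' @slot heightmap "boundary" (1 - boundary distance) or "combined"
#'   (0.5 * (center + 1 - boundary)).
#' @export
setClass("AISConfig", representation(
  centerThreshold = "numeric", boundaryThreshold = "numeric",
  foregroundThreshold = "numeric", minObjectSize = "numeric",
  heightmap = "character"
), validity = function(object) {
  th <- c(object@centerThreshold, object@boundaryThreshold,
          object@foregroundThreshold)
  if (any(th <= 0) || any(th >= 1)) return("thresholds must lie in (0, 1)")
  if (!object@heightmap %in% c("boundary", "combined"))
    return("heightmap must be 'boundary' or 'combined'")
  TRUE
})

#' AMGConfig: proposal generation and filtering parameters
#'
#' @slot pointsPerSide grid resolution (pointsPerSide^2 prompts per image).
#' @slot iouThreshold drop candidates with lower predicted IoU.
#' @slot stabilityThreshold drop candidates with lower stability score.
#' @slot stabilityOffset logit offset delta used by the stability score.
#' @slot nmsIou suppression threshold for overlapping kept masks.
#' @slot minObjectSize drop candidates smaller than this many pixels.
#' @export
setClass("AMGConfig", representation(
  pointsPerSide = "integer", iouThreshold = "numeric",
  stabilityThreshold = "numeric", stabilityOffset = "numeric",
  nmsIou = "numeric", minObjectSize = "numeric"
), validity = function(object) {
  if (object@pointsPerSide < 1L) return("pointsPerSide must be >= 1")
  TRUE
})

#' TrainConfig: hyperparameters of the iterative training scheme
#'
#' @slot batchSize images per gradient step.
#' @slot nObjectsPerImage objects sampled per image per iteration.
#' @slot nSubIterations correction sub-iterations per object (initial prompt
#'   plus nSubIterations - 1 correction rounds).
#' @slot maskPromptProbability probability of feeding the previous mask
#'   prediction back as a prompt from sub-iteration 1 on.
#' @slot patchShape training patch (smaller images are zero padded).
#' @slot learningRate initial Adam learning rate.
#' @slot lrFactor,lrPatience ReduceLROnPlateau schedule.
#' @slot maxEpochs,earlyStoppingPatience run length control.
#' @slot freeze character subset of c("encoder", "prompt_encoder",
#'   "mask_decoder"); frozen groups receive no updates.
#' @slot nValPoints points per object used by the validation prompt.
#' @slot seed RNG seed for the whole run.
#' @export
setClass("TrainConfig", representation(
  batchSize = "integer", nObjectsPerImage = "integer",
  nSubIterations = "integer", maskPromptProbability = "numeric",
  patchShape = "integer", learningRate = "numeric", lrFactor = "numeric",
  lrPatience = "integer", maxEpochs = "integer",
  earlyStoppingPatience = "integer", freeze = "character",
  nValPoints = "integer", seed = "integer"
))

#' TrainState: bookkeeping of one training run
#'
#' @slot losses data.frame with one row per iteration (maskLoss, iouLoss,
#'   aisLoss, lr).
#' @slot valHistory numeric validation metric per epoch.
#' @slot bestEpoch epoch of the best validation metric (its weights are
#'   restored into the model at the end of fitting).
#' @slot config the TrainConfig used.
#' @export
setClass("TrainState", representation(
  losses = "data.frame", valHistory = "numeric", bestEpoch = "integer",
  config = "TrainConfig"
))

#' SyntheticSpec: parameters of the synthetic microscopy generator
#'
#' @slot shape integer (H, W), (Z, H, W) or (T, H, W).
#' @slot nObjects number of objects.
#' @slot radiusRange pixel radius range (>= 2).
#' @slot touchingFraction fraction of objects placed adjacent to another
#'   object (sharing a boundary without overlap).
#' @slot fgIntensity,bgIntensity mean intensities of objects and background.
#' @slot noiseSigma additive Gaussian noise level.
#' @slot driftPerFrame maximal per-axis centroid drift (time series only).
#' @slot seed RNG seed; output is a pure function of the spec.
#' @export
setClass("SyntheticSpec", representation(
  shape = "integer", nObjects = "integer", radiusRange = "numeric",
  touchingFraction = "numeric", fgIntensity = "numeric",
  bgIntensity = "numeric", noiseSigma = "numeric", driftPerFrame = "numeric",
  seed = "integer"
), validity = function(object) {
  if (!length(object@shape) %in% c(2L, 3L))
    return("shape must be (H, W), (Z, H, W) or (T, H, W)")
  if (object@nObjects < 0L) return("nObjects must be >= 0")
  if (any(object@radiusRange < 2)) return("radii must be >= 2 px")
  if (object@touchingFraction < 0 || object@touchingFraction > 1)
    return("touchingFraction must be in [0, 1]")
  TRUE
})

#' PromptableModel: the contract every segmentation backend fulfils
#'
#' A promptable model splits into a prompt-independent image encoder
#' ([embedImage()]) and a light decoder ([predictMasks()]) that turns an
#' embedding plus prompts into mask logits with a self-estimated IoU.
#' Implementations: [oracleModel()] (deterministic test double driven by
#' ground truth) and [toyPromptableModel()] (small trainable convolutional
#' model with an additional AIS decoder head).
#'
#' @export
setClass("PromptableModel", representation("VIRTUAL"))

#' @rdname PromptableModel
#' @slot labels ground-truth label matrix the oracle answers from.
#' @slot behavior "exact", "dilate" or "erode".
#' @slot k structuring-element radius for dilate/erode.
#' @export
setClass("OracleModel", contains = "PromptableModel", representation(
  labels = "matrix", behavior = "character", k = "integer"
))

#' @rdname PromptableModel
#' @slot arch architecture description (channel widths, scale, prompt sigma).
#' @slot weights environment holding the parameter matrices (reference
#'   semantics so that training updates the model in place).
#' @export
setClass("ToyPromptableModel", contains = "PromptableModel", representation(
  arch = "list", weights = "environment"
))

#' InteractiveEvalResult: one simulated interactive annotation run
#'
#' @slot startMode "point" or "box".
#' @slot useMaskPrompt whether the previous mask was fed back each iteration.
#' @slot msaPerIteration mSA after the initial prompt (entry 1) and after
#'   each correction iteration.
#' @slot trace list of per-iteration assembled label images (optional).
#' @export
setClass("InteractiveEvalResult", representation(
  startMode = "character", useMaskPrompt = "logical",
  msaPerIteration = "numeric", trace = "list"
))
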