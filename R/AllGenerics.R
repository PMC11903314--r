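#' Compute the prompt-independent embedding of an image
#'
#' The encoder is applied once per image; all subsequent mask predictions for
#' changing prompts reuse the embedding.
#'
#' @param model a [PromptableModel-class].
#' @param image numeric matrix (H x W) or array (H x W x C), C <= 3.
#' @return an [ImageEmbedding-class].
#' @export
setGeneric("embedImage", function(model, image) standardGeneric("embedImage"))

#' Predict object masks from an embedding and prompts
#'
#' @param model a [PromptableModel-class].
#' @param embedding an [ImageEmbedding-class] from [embedImage()].
#' @param prompts a [PromptSet-class] with at least one point or a box.
#' @param multimask if TRUE return exactly three candidate predictions
#'   (resolving single-point ambiguity), otherwise one.
#' @return list of [MaskPrediction-class] (length 3 if `multimask`, else 1).
#' @export
setGeneric("predictMasks", function(model, embedding, prompts,
                                    multimask = FALSE)
  standardGeneric("predictMasks"))

#' Predict the three AIS channels for an image
#'
#' Returns foreground probabilities and normalized center/boundary distances;
#' decoded into instances by [aisSegment()]. The oracle model returns the
#' ideal channels of its ground truth, the toy model the output of its AIS
#' decoder head.
#'
#' @param model a [PromptableModel-class].
#' @param embedding an [ImageEmbedding-class].
#' @return a [DistanceTargets-class].
#' @export
setGeneric("aisPredict", function(model, embedding)
  standardGeneric("aisPredict"))

#' Names of the model's trainable parameter groups
#'
#' @param model a [PromptableModel-class].
#' @return character vector, subset of c("encoder", "prompt_encoder",
#'   "mask_decoder", "ais_decoder").
#' @export
setGeneric("trainableGroups", function(model)
  standardGeneric("trainableGroups"))
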