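## evaluation: simulated interactive annotation — the 7-iteration
## correction protocol with per-iteration mSA.

assembleLabelImage <- function(masks, scores, shape) {
  out <- matrix(0L, shape[1L], shape[2L])
  ord <- order(scores)  # ascending: higher scores painted last, win overlaps
  for (i in ord) out[masks[[i]]] <- i
  out
}

#' Simulate interactive segmentation of one image
#'
#' For every ground-truth object the model is prompted with a single point
#' or the bounding box (`startMode`), then corrected for `nIterations`
#' rounds: a positive point is sampled from the missed area and a negative
#' point from the spurious area, prompts accumulate, and the model is
#' re-run (with the previous mask as an additional prompt iff
#' `useMaskPrompt`). After every round all per-object masks are assembled
#' into a label image (overlaps resolved by predicted-IoU order) and
#' scored by mSA against the ground truth.
#'
#' @param model a [PromptableModel-class].
#' @param image the image to segment.
#' @param gt integer label matrix with at least one object.
#' @param startMode "point" or "box".
#' @param nIterations number of correction rounds (0 = initial prompt
#'   only).
#' @param useMaskPrompt always feed the previous mask back when TRUE.
#' @param seed RNG seed for all prompt sampling.
#' @param keepTrace store the per-iteration assembled label images.
#' @return an [InteractiveEvalResult-class] with `nIterations + 1` mSA
#'   values.
#' @export
simulateInteractiveSegmentation <- function(model, image, gt,
                                            startMode = c("point", "box"),
                                            nIterations = 7L,
                                            useMaskPrompt = FALSE,
                                            seed = NULL,
                                            keepTrace = FALSE) {
  startMode <- match.arg(startMode)
  ids <- objectIds(gt)
  if (length(ids) == 0L) stop("ground truth contains no objects")
  withSeed(seed, {
    emb <- embedImage(model, image)
    state <- lapply(ids, function(id) {
      gtMask <- gt == id
      prompts <- sampleInitialPrompt(gtMask, startMode)
      pred <- tryCatch(
        predictMasks(model, emb, prompts,
                     multimask = startMode == "point"),
        error = function(e) stop("prediction failed for object ", id, ": ",
                                 conditionMessage(e)))
      best <- which.max(vapply(pred, function(p) p@iouEstimate, numeric(1)))
      list(gtMask = gtMask, prompts = prompts, logits = pred[[best]]@logits,
           score = pred[[best]]@iouEstimate)
    })
    msa <- numeric(nIterations + 1L)
    trace <- list()
    record <- function(iter) {
      masks <- lapply(state, function(s) s$logits > 0)
      scores <- vapply(state, function(s) s$score, numeric(1))
      assembled <- assembleLabelImage(masks, scores, dim(gt))
      msa[iter] <<- meanSegmentationAccuracy(assembled, gt)
      if (keepTrace) trace[[iter]] <<- assembled
    }
    record(1L)
    for (k in seq_len(nIterations)) {
      state <- lapply(seq_along(state), function(i) {
        s <- state[[i]]
        corr <- sampleCorrectionPoints(s$gtMask, s$logits > 0)
        mp <- if (useMaskPrompt) {
          lp <- padToScale(s$logits, emb@scale)
          downsampleLogits(lp, geom(nrow(lp), ncol(lp), emb@scale))
        }
        s$prompts <- accumulatePrompts(s$prompts,
                                       rbind(corr$positive, corr$negative),
                                       positive = c(TRUE, FALSE),
                                       maskPrompt = mp)
        pred <- tryCatch(
          predictMasks(model, emb, s$prompts, multimask = FALSE),
          error = function(e) stop("prediction failed for object ", ids[i],
                                   ": ", conditionMessage(e)))
        s$logits <- pred[[1L]]@logits
        s$score <- pred[[1L]]@iouEstimate
        s
      })
      record(k + 1L)
    }
    new("InteractiveEvalResult", startMode = startMode,
        useMaskPrompt = useMaskPrompt, msaPerIteration = msa,
        trace = trace)
  })
}

setMethod("show", "InteractiveEvalResult", function(object) {
  cat("InteractiveEvalResult (start =", object@startMode, "):\n  mSA",
      paste(sprintf("%.3f", object@msaPerIteration), collapse = " "), "\n")
})

#' Evaluate the interactive protocol over a dataset
#'
#' Runs [simulateInteractiveSegmentation()] for every image (and both
#' start modes by default) and aggregates per-iteration mSA across images
#' with [datasetMean()]; repeated seeds quantify the sampling randomness.
#'
#' @param model a [PromptableModel-class].
#' @param images,gts parallel lists of images and label matrices.
#' @param startModes modes to evaluate.
#' @param nIterations correction rounds.
#' @param useMaskPrompt feed previous masks back each round.
#' @param seeds one seed per repetition.
#' @return list(perImage = data.frame(image, startMode, seed, iteration,
#'   msa), summary = data.frame(startMode, iteration, mean, sd)).
#' @export
evaluateInteractiveDataset <- function(model, images, gts,
                                       startModes = c("point", "box"),
                                       nIterations = 7L,
                                       useMaskPrompt = FALSE,
                                       seeds = 1L) {
  if (length(images) == 0L) stop("empty evaluation dataset")
  stopifnot(length(images) == length(gts))
  rows <- list()
  mdl <- model
  for (sd0 in seeds) {
    for (mode in startModes) {
      for (i in seq_along(images)) {
        m <- if (is.list(mdl)) mdl[[i]] else mdl
        res <- simulateInteractiveSegmentation(
          m, images[[i]], gts[[i]], startMode = mode,
          nIterations = nIterations, useMaskPrompt = useMaskPrompt,
          seed = sd0 + 1000L * i)
        rows[[length(rows) + 1L]] <- data.frame(
          image = i, startMode = mode, seed = sd0,
          iteration = seq_len(nIterations + 1L) - 1L,
          msa = res@msaPerIteration)
      }
    }
  }
  perImage <- do.call(rbind, rows)
  summary <- aggregate(msa ~ startMode + iteration, perImage,
                       function(x) c(mean = mean(x), sd = sd(x)))
  summary <- data.frame(startMode = summary$startMode,
                        iteration = summary$iteration,
                        mean = summary$msa[, "mean"],
                        sd = summary$msa[, "sd"])
  list(perImage = perImage, summary = summary)
}
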