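## training: iterative interactive-segmentation fine-tuning with simulated
## correction clicks, interleaved with AIS-decoder training; losses,
## validation, plateau scheduling and early stopping.

setMethod("show", "TrainState", function(object) {
  cat("TrainState:", nrow(object@losses), "iterations over",
      length(object@valHistory), "epochs; best epoch", object@bestEpoch,
      sprintf("(val %.4f)\n", max(object@valHistory)))
})

#' Construct a training configuration
#'
#' @param batchSize images per gradient step.
#' @param nObjectsPerImage objects sampled per image (all objects, capped,
#'   sampled without replacement).
#' @param nSubIterations prompt rounds per object: the initial prompt plus
#'   nSubIterations - 1 correction rounds.
#' @param maskPromptProbability probability of feeding the previous mask
#'   prediction back as an additional prompt (from round 1 on).
#' @param patchShape square training patch in pixels; smaller images are
#'   zero padded.
#' @param learningRate initial Adam learning rate.
#' @param lrFactor,lrPatience multiply the rate by `lrFactor` when the
#'   validation metric fails to improve for `lrPatience` epochs.
#' @param maxEpochs upper bound on training epochs.
#' @param earlyStoppingPatience stop after this many epochs without
#'   validation improvement.
#' @param freeze parameter groups excluded from updates, subset of
#'   c("encoder", "prompt_encoder", "mask_decoder").
#' @param nValPoints positive points per object used in validation prompts.
#' @param seed RNG seed of the run.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(batchSize = 2L, nObjectsPerImage = 8L,
                        nSubIterations = 8L, maskPromptProbability = 0.5,
                        patchShape = 512L, learningRate = 2e-3,
                        lrFactor = 0.5, lrPatience = 3L, maxEpochs = 100L,
                        earlyStoppingPatience = 10L, freeze = character(),
                        nValPoints = 1L, seed = 1L) {
  stopifnot(maskPromptProbability >= 0, maskPromptProbability <= 1,
            batchSize >= 1L, nObjectsPerImage >= 1L, nSubIterations >= 1L)
  bad <- setdiff(freeze, c("encoder", "prompt_encoder", "mask_decoder"))
  if (length(bad)) stop("unknown freeze group(s): ", paste(bad, collapse = ", "))
  new("TrainConfig", batchSize = as.integer(batchSize),
      nObjectsPerImage = as.integer(nObjectsPerImage),
      nSubIterations = as.integer(nSubIterations),
      maskPromptProbability = maskPromptProbability,
      patchShape = as.integer(patchShape), learningRate = learningRate,
      lrFactor = lrFactor, lrPatience = as.integer(lrPatience),
      maxEpochs = as.integer(maxEpochs),
      earlyStoppingPatience = as.integer(earlyStoppingPatience),
      freeze = freeze, nValPoints = as.integer(nValPoints),
      seed = as.integer(seed))
}

## ---- losses ----------------------------------------------------------

#' Dice loss between predicted probabilities and a target map
#'
#' Soft Dice with a squared denominator, `1 - (2 sum(p t) + eps) /
#' (sum(p^2) + sum(t^2) + eps)`; 0 for a perfect hard prediction and
#' identical to the mask-overlap Dice for binary inputs.
#'
#' @param p numeric predictions in \[0, 1\].
#' @param target numeric target in \[0, 1\] (same shape).
#' @param eps smoothing constant.
#' @return numeric loss in \[0, 1\].
#' @export
diceLoss <- function(p, target, eps = 1e-6) {
  1 - (2 * sum(p * target) + eps) / (sum(p^2) + sum(target^2) + eps)
}

## gradient of diceLoss wrt p
diceLossGrad <- function(p, target, eps = 1e-6) {
  num <- 2 * sum(p * target) + eps
  den <- sum(p^2) + sum(target^2) + eps
  -(2 * target * den - num * 2 * p) / den^2
}

#' Squared-error loss between estimated and true IoU
#'
#' @param estimate predicted IoU.
#' @param trueIou measured IoU of the thresholded prediction.
#' @return squared error.
#' @export
iouRegressionLoss <- function(estimate, trueIou) {
  (estimate - trueIou)^2
}

#' AIS decoder loss
#'
#' Mean of three Dice losses over the predicted channels; the two distance
#' channels are evaluated only on target-foreground pixels (loss masking),
#' the foreground channel everywhere.
#'
#' @param pred,target [DistanceTargets-class] objects of the same shape.
#' @return numeric loss in \[0, 1\].
#' @export
aisLoss <- function(pred, target) {
  fgSel <- target@foreground > 0.5
  maskedDice <- function(p, t) {
    if (!any(fgSel)) return(0)
    diceLoss(p[fgSel], t[fgSel])
  }
  (diceLoss(pred@foreground, target@foreground) +
     maskedDice(pred@center, target@center) +
     maskedDice(pred@boundary, target@boundary)) / 3
}

## ---- shared helpers --------------------------------------------------

padPair <- function(image, labels, patch) {
  d <- dim(labels)
  if (d[1L] > patch || d[2L] > patch)
    stop("image larger than the training patch shape")
  img <- matrix(0, patch, patch)
  img[seq_len(d[1L]), seq_len(d[2L])] <- if (is.matrix(image)) image
                                         else image[, , 1L]
  lab <- matrix(0L, patch, patch)
  lab[seq_len(d[1L]), seq_len(d[2L])] <- labels
  list(image = img, labels = lab)
}

downsampleLogits <- function(logits, g) {
  g$Ph %*% logits %*% t(g$Pw)
}

## per-term backward pass through mask decoder: dice + IoU losses on one
## prediction channel, scaled by `wgt`. Returns dE contribution.
maskLossBackward <- function(w, dec, chan, gtVec, wgt, g, grads) {
  z <- dec$Lfull[, chan]
  p <- sigmoid(z)
  dP <- diceLossGrad(p, gtVec)
  dZ <- dP * p * (1 - p) * wgt
  est <- dec$iouEst[chan]
  trueIou <- {
    inter <- sum((z > 0) & (gtVec > 0.5))
    uni <- sum((z > 0) | (gtVec > 0.5))
    if (uni == 0L) 1 else inter / uni
  }
  dEstLogit <- 2 * (est - trueIou) * est * (1 - est) * wgt
  dLfull <- matrix(0, length(z), 4L)
  dLfull[, chan] <- dZ
  dIou <- numeric(4L)
  dIou[chan] <- dEstLogit
  bk <- decBackward(w, dec, dLfull, dIou, g, grads)
  list(dE = bk$dE, dH1 = bk$dH1, dice = diceLoss(p, gtVec),
       iou = iouRegressionLoss(est, trueIou))
}

## ---- training iterations --------------------------------------------

#' One interactive-segmentation training iteration
#'
#' For every image: embed once; sample objects; per object start from a
#' point or box prompt (fair coin), predict (three masks for a single
#' point, scoring only the one with the highest IoU estimate), then run
#' correction rounds: sample a positive/negative pair from the current
#' errors, accumulate prompts, optionally feed the previous mask back
#' (probability `maskPromptProbability`), re-predict a single mask. Dice
#' and IoU-regression losses from all rounds are averaged and one gradient
#' step updates every non-frozen group.
#'
#' @param model a [ToyPromptableModel][PromptableModel-class].
#' @param images,labelsList parallel lists of images and label matrices.
#' @param config a [trainConfig()].
#' @param opt Adam state from [adamInit()] internals; a fresh one is
#'   created (single-step use) when NULL.
#' @return list with maskLoss, iouLoss, loss (their sum), and a `trace`
#'   data.frame (object, subIteration, nPoints, hasBox, usedMaskPrompt)
#'   for prompt bookkeeping.
#' @export
interactiveTrainIteration <- function(model, images, labelsList, config,
                                      opt = NULL) {
  w <- model@weights
  grads <- zeroGrads(w)
  trace <- list()
  diceSum <- 0
  iouSum <- 0
  nTerms <- 0L
  ## count loss terms upfront so each backward carries its mean weight
  sampledIds <- lapply(labelsList, function(lab) {
    ids <- objectIds(lab)
    if (length(ids) == 0L) return(integer())
    if (length(ids) > config@nObjectsPerImage)
      sample(ids, config@nObjectsPerImage)
    else sample(ids)
  })
  nTotal <- sum(lengths(sampledIds)) * config@nSubIterations
  if (nTotal == 0L) {
    warning("no objects in any training image; iteration skipped")
    return(list(maskLoss = NA_real_, iouLoss = NA_real_, loss = NA_real_,
                trace = data.frame()))
  }
  wgt <- 1 / nTotal
  for (b in seq_along(images)) {
    ids <- sampledIds[[b]]
    if (length(ids) == 0L) {
      warning("training image ", b, " has no objects; skipped")
      next
    }
    pp <- padPair(images[[b]], labelsList[[b]], config@patchShape)
    fw <- toyEmbedInternal(model, pp$image)
    g <- fw$g
    E <- fw$cache$E
    H1 <- fw$cache$H1
    dE <- matrix(0, nrow(E), ncol(E))
    dH1 <- matrix(0, nrow(H1), ncol(H1))
    for (id in ids) {
      gtMask <- pp$labels == id
      gtVec <- as.numeric(gtMask)
      mode <- if (runif(1) < 0.5) "point" else "box"
      prompts <- sampleInitialPrompt(gtMask, mode)
      prevLogits <- NULL
      for (k in seq_len(config@nSubIterations)) {
        usedMask <- FALSE
        if (k > 1L) {
          predMask <- matrix(prevLogits > 0, g$H, g$W)
          corr <- sampleCorrectionPoints(gtMask, predMask)
          usedMask <- runif(1) < config@maskPromptProbability
          prompts <- accumulatePrompts(
            prompts, rbind(corr$positive, corr$negative),
            positive = c(TRUE, FALSE),
            maskPrompt = if (usedMask) downsampleLogits(
              matrix(prevLogits, g$H, g$W), g))
          if (!usedMask) prompts@maskPrompt <- matrix(numeric(), 0L, 0L)
        }
        multi <- k == 1L && mode == "point"
        dec <- decForward(w, E, rasterPrompts(prompts, g,
                                              model@arch$promptSigma), g, H1)
        chan <- if (multi) 1L + which.max(dec$iouEst[2:4]) else 1L
        bk <- maskLossBackward(w, dec, chan, gtVec, wgt, g, grads)
        dE <- dE + bk$dE
        dH1 <- dH1 + bk$dH1
        diceSum <- diceSum + bk$dice
        iouSum <- iouSum + bk$iou
        nTerms <- nTerms + 1L
        prevLogits <- dec$Lfull[, chan]
        trace[[length(trace) + 1L]] <- data.frame(
          image = b, object = id, subIteration = k - 1L,
          nPoints = nPoints(prompts), hasBox = hasBox(prompts),
          usedMaskPrompt = usedMask)
      }
    }
    encBackward(w, fw$cache, dE, g, grads, dH1)
  }
  maskLoss <- diceSum / nTerms
  iouLoss <- iouSum / nTerms
  if (!is.finite(maskLoss + iouLoss))
    stop("non-finite interactive loss; aborting")
  if (is.null(opt)) opt <- adamInit(w)
  adamStep(w, grads, opt, config@learningRate, config@freeze)
  list(maskLoss = maskLoss, iouLoss = iouLoss, loss = maskLoss + iouLoss,
       trace = do.call(rbind, trace))
}

#' One AIS-decoder training iteration
#'
#' Uses the same images (and padding) as the interactive iteration: the
#' decoder targets are derived from the ground truth, the loss is
#' [aisLoss()], and the gradient step updates the encoder (unless frozen)
#' and the AIS decoder head.
#'
#' @inheritParams interactiveTrainIteration
#' @return list(loss = mean AIS loss over the batch).
#' @export
aisTrainIteration <- function(model, images, labelsList, config,
                              opt = NULL) {
  w <- model@weights
  grads <- zeroGrads(w)
  lossSum <- 0
  n <- length(images)
  for (b in seq_len(n)) {
    pp <- padPair(images[[b]], labelsList[[b]], config@patchShape)
    target <- computeDistanceTargets(pp$labels)
    fw <- toyEmbedInternal(model, pp$image)
    g <- fw$g
    af <- aisForward(w, fw$cache$E, g, fw$cache$H1)
    tg <- cbind(as.numeric(target@foreground), as.numeric(target@center),
                as.numeric(target@boundary))
    fgSel <- tg[, 1L] > 0.5
    dProbs <- matrix(0, nrow(af$probs), 3L)
    lossImg <- 0
    for (ch in 1:3) {
      sel <- if (ch == 1L) rep(TRUE, nrow(tg)) else fgSel
      if (!any(sel)) next
      p <- af$probs[sel, ch]
      t0 <- tg[sel, ch]
      lossImg <- lossImg + diceLoss(p, t0) / 3
      dProbs[sel, ch] <- diceLossGrad(p, t0) / 3
    }
    dOfull <- dProbs * af$probs * (1 - af$probs) / n
    bk <- aisBackward(w, af, dOfull, g, grads)
    encBackward(w, fw$cache, bk$dE, g, grads, bk$dH1)
    lossSum <- lossSum + lossImg
  }
  loss <- lossSum / n
  if (!is.finite(loss)) stop("non-finite AIS loss; aborting")
  if (is.null(opt)) opt <- adamInit(w)
  adamStep(w, grads, opt, config@learningRate, config@freeze)
  list(loss = loss)
}

#' Validation metric for training
#'
#' Interactive component: every object is prompted with its bounding box
#' plus `nValPoints` random positive points and scored by the Dice overlap
#' of the thresholded prediction; automatic component: 1 - [aisLoss()].
#' The two are added. Deterministic for a fixed seed.
#'
#' @param model a [PromptableModel-class].
#' @param images,labelsList validation images and labels.
#' @param config a [trainConfig()] (patch shape, nValPoints).
#' @param seed seed for the validation point sampling.
#' @return numeric score (higher is better).
#' @export
validateModel <- function(model, images, labelsList, config = trainConfig(),
                          seed = 0L) {
  withSeed(seed, {
    diceVals <- numeric()
    aisVals <- numeric()
    for (b in seq_along(images)) {
      pp <- padPair(images[[b]], labelsList[[b]], config@patchShape)
      emb <- embedImage(model, pp$image)
      for (id in objectIds(pp$labels)) {
        gtMask <- pp$labels == id
        pts <- do.call(rbind, lapply(seq_len(config@nValPoints),
                                     function(i) samplePixel(gtMask)))
        prompts <- promptSet(points = pts, positive = TRUE,
                             box = boxFromMask(gtMask))
        pred <- predictMasks(model, emb, prompts)[[1L]]
        diceVals <- c(diceVals, diceScore(pred@logits > 0, gtMask))
      }
      target <- computeDistanceTargets(pp$labels)
      aisVals <- c(aisVals, 1 - aisLoss(aisPredict(model, emb), target))
    }
    mean(if (length(diceVals)) diceVals else 0) + mean(aisVals)
  })
}

#' Fit the toy promptable model
#'
#' Alternates interactive and AIS iterations over shuffled mini-batches,
#' validates every epoch, lowers the learning rate on plateaus, stops
#' early when validation stalls and restores the best-validation weights.
#'
#' @param model a [ToyPromptableModel][PromptableModel-class] (updated in
#'   place).
#' @param images,labelsList training images and label matrices.
#' @param valImages,valLabels validation data.
#' @param config a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return a [TrainState-class].
#' @export
fitPromptable <- function(model, images, labelsList, valImages, valLabels,
                          config = trainConfig(), verbose = FALSE) {
  if (length(images) == 0L) stop("empty training set")
  withSeed(config@seed, {
    opt <- adamInit(model@weights)
    lr <- config@learningRate
    losses <- list()
    valHistory <- numeric()
    bestVal <- -Inf
    bestEpoch <- 0L
    bestW <- weightsAsList(model)
    sinceBest <- 0L
    sincePlateau <- 0L
    it <- 0L
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample(length(images))
      starts <- seq(1L, length(ord), by = config@batchSize)
      cfgLr <- config
      cfgLr@learningRate <- lr
      for (s in starts) {
        sel <- ord[s:min(s + config@batchSize - 1L, length(ord))]
        ia <- interactiveTrainIteration(model, images[sel],
                                        labelsList[sel], cfgLr, opt)
        aa <- aisTrainIteration(model, images[sel], labelsList[sel],
                                cfgLr, opt)
        it <- it + 1L
        losses[[it]] <- data.frame(iteration = it, epoch = epoch,
                                   maskLoss = ia$maskLoss,
                                   iouLoss = ia$iouLoss,
                                   aisLoss = aa$loss, lr = lr)
      }
      val <- validateModel(model, valImages, valLabels, config,
                           seed = config@seed + 7L)
      valHistory <- c(valHistory, val)
      if (verbose) {
        message(sprintf("epoch %d: val %.4f lr %.2e", epoch, val, lr))
      }
      if (val > bestVal + 1e-8) {
        bestVal <- val
        bestEpoch <- epoch
        bestW <- weightsAsList(model)
        sinceBest <- 0L
        sincePlateau <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        sincePlateau <- sincePlateau + 1L
        if (sincePlateau >= config@lrPatience) {
          lr <- lr * config@lrFactor
          sincePlateau <- 0L
        }
        if (sinceBest >= config@earlyStoppingPatience) break
      }
    }
    restoreWeights(model, bestW)
    new("TrainState", losses = do.call(rbind, losses),
        valHistory = valHistory, bestEpoch = bestEpoch, config = config)
  })
}
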