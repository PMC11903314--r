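## metrics: IoU, Dice, instance matching, SA(t) and mean segmentation
## accuracy — the evaluation currency of the whole package.

#' Intersection over union of two binary masks
#'
#' Defined as 1.0 when both masks are empty.
#' @param a,b logical matrices of the same shape.
#' @return numeric in \[0, 1\].
#' @export
maskIoU <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(1.0)
  inter / uni
}

#' Dice score of two binary masks
#'
#' 2|a n b| / (|a| + |b|); 1.0 when both masks are empty.
#' @param a,b logical matrices of the same shape.
#' @return numeric in \[0, 1\].
#' @export
diceScore <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  s <- sum(a) + sum(b)
  if (s == 0L) return(1.0)
  2 * sum(a & b) / s
}

## Pairwise IoU between the instances of two label images. Returns a
## data.frame (predId, gtId, iou) for every overlapping pair, plus the
## per-id areas as attributes.
iouPairs <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("label image shapes differ")
  predIds <- objectIds(pred)
  gtIds <- objectIds(gt)
  out <- data.frame(predId = integer(), gtId = integer(), iou = numeric())
  areaP <- setNames(as.numeric(table(factor(pred[pred > 0], levels = predIds))),
                    predIds)
  areaG <- setNames(as.numeric(table(factor(gt[gt > 0], levels = gtIds))),
                    gtIds)
  sel <- pred > 0 & gt > 0
  if (any(sel)) {
    tab <- table(factor(pred[sel], levels = predIds),
                 factor(gt[sel], levels = gtIds))
    idx <- which(tab > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      inter <- tab[idx]
      pi <- predIds[idx[, 1L]]
      gi <- gtIds[idx[, 2L]]
      iou <- inter / (areaP[as.character(pi)] + areaG[as.character(gi)] - inter)
      out <- data.frame(predId = pi, gtId = gi, iou = as.numeric(iou))
      out <- out[order(out$predId, out$gtId), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "predIds") <- predIds
  attr(out, "gtIds") <- gtIds
  out
}

## Square-cost Hungarian algorithm (shortest augmenting path), minimizing.
## cost: n x n matrix, finite. Returns integer vector a with a[j] = row
## assigned to column j.
solveAssignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j + 1]: row assigned to column j (0 = virtual)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1L]
}

## One-to-one matching of overlapping pairs with iou > t, maximizing total
## IoU. For t >= 0.5 the admissible pairs already form a matching (two
## disjoint predictions cannot both overlap one object by more than half);
## below that a Hungarian assignment resolves the general case.
matchPairs <- function(pairs, t) {
  adm <- pairs[pairs$iou > t, , drop = FALSE]
  if (nrow(adm) == 0L) return(adm)
  if (t >= 0.5 && !anyDuplicated(adm$predId) && !anyDuplicated(adm$gtId))
    return(adm)
  pi <- unique(adm$predId)
  gi <- unique(adm$gtId)
  n <- max(length(pi), length(gi))
  big <- 2
  cost <- matrix(big, n, n)
  w <- matrix(0, n, n)
  ri <- match(adm$predId, pi)
  ci <- match(adm$gtId, gi)
  cost[cbind(ri, ci)] <- big - adm$iou
  w[cbind(ri, ci)] <- adm$iou
  a <- solveAssignment(cost)
  keep <- data.frame(predId = integer(), gtId = integer(), iou = numeric())
  for (j in seq_len(n)) {
    i <- a[j]
    if (i <= length(pi) && j <= length(gi) && w[i, j] > 0) {
      keep <- rbind(keep, data.frame(predId = pi[i], gtId = gi[j],
                                     iou = w[i, j]))
    }
  }
  keep <- keep[order(keep$predId, keep$gtId), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Match predicted to ground-truth instances at an IoU threshold
#'
#' One-to-one matching maximizing total IoU among pairs with IoU strictly
#' greater than `t` (a tie at `t` counts as unmatched). Unmatched
#' predictions are false positives, unmatched ground-truth objects false
#' negatives.
#'
#' @param pred,gt label matrices of the same shape.
#' @param t IoU threshold in \[0, 1\].
#' @return a [MatchResult-class].
#' @export
matchInstances <- function(pred, gt, t) {
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  pairs <- iouPairs(pred, gt)
  matched <- matchPairs(pairs, t)
  np <- length(attr(pairs, "predIds"))
  ng <- length(attr(pairs, "gtIds"))
  new("MatchResult", threshold = t, tp = nrow(matched),
      fp = np - nrow(matched), fn = ng - nrow(matched), pairs = matched)
}

saFromCounts <- function(tp, fp, fn) {
  denom <- tp + fp + fn
  if (denom == 0L) return(1.0)  # both images empty
  tp / denom
}

#' Segmentation accuracy SA(t)
#'
#' SA(t) = TP(t) / (TP(t) + FP(t) + FN(t)) after instance matching at IoU
#' threshold t. Both images empty yields 1.0; exactly one empty yields 0.0.
#'
#' @inheritParams matchInstances
#' @return numeric in \[0, 1\].
#' @export
segmentationAccuracy <- function(pred, gt, t) {
  m <- matchInstances(pred, gt, t)
  saFromCounts(m@tp, m@fp, m@fn)
}

#' Segmentation accuracy at IoU threshold 0.5
#'
#' The less stringent single-threshold variant SA(0.5).
#' @param pred,gt label matrices of the same shape.
#' @return numeric in \[0, 1\].
#' @export
segmentationAccuracyAt50 <- function(pred, gt) {
  segmentationAccuracy(pred, gt, 0.5)
}

#' Mean segmentation accuracy (mSA)
#'
#' Mean of SA(t) over the ten thresholds t = 0.50, 0.55, ..., 0.95. Above
#' t = 0.5 the matching is unique, so the pairwise IoU table is computed
#' once and swept over thresholds.
#'
#' @param pred,gt label matrices of the same shape.
#' @return numeric in \[0, 1\].
#' @export
meanSegmentationAccuracy <- function(pred, gt) {
  pairs <- iouPairs(pred, gt)
  np <- length(attr(pairs, "predIds"))
  ng <- length(attr(pairs, "gtIds"))
  ts <- seq(0.5, 0.95, by = 0.05)
  sas <- vapply(ts, function(t) {
    tp <- sum(pairs$iou > t)
    saFromCounts(tp, np - tp, ng - tp)
  }, numeric(1))
  mean(sas)
}

#' Unweighted mean of per-image scores
#'
#' @param scores numeric vector of per-image scores.
#' @return their mean.
#' @export
datasetMean <- function(scores) {
  if (length(scores) == 0L) stop("no scores to average")
  mean(scores)
}
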