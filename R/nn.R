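## nn: minimal convolutional machinery for the toy promptable model.
## Everything is dense matrix algebra: 3x3 convolutions via im2col patch
## matrices, pooling/upsampling via small resampling matrices, gradients
## hand-derived. Feature maps are stored as (H*W) x C matrices in
## column-major pixel order.

sigmoid <- function(x) plogis(x)
relu <- function(x) pmax(x, 0)

## cache of geometry helpers (patch indices, pooling matrices) per shape
.geomCache <- new.env(parent = emptyenv())

## Linear indices of the 3x3 neighborhood of every pixel (0 = outside,
## zero padding). Column-major pixel order; offset order dc slow, dr fast.
convIdx <- function(H, W) {
  key <- paste0("idx:", H, "x", W)
  if (!is.null(.geomCache[[key]])) return(.geomCache[[key]])
  r <- rep(seq_len(H), W)
  c0 <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  j <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    j <- j + 1L
    rr <- r + dr
    cc <- c0 + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    v <- integer(H * W)
    v[ok] <- (cc[ok] - 1L) * H + rr[ok]
    idx[, j] <- v
  }
  .geomCache[[key]] <- idx
  idx
}

## X: (H*W) x C -> patches (H*W) x (9C); column (c-1)*9 + j.
im2col <- function(X, idx) {
  C <- ncol(X)
  n <- nrow(idx)
  out <- matrix(0, n, 9L * C)
  for (j in 1:9) {
    iv <- idx[, j]
    ok <- iv > 0L
    iv[!ok] <- 1L
    block <- X[iv, , drop = FALSE]
    if (!all(ok)) block[!ok, ] <- 0
    out[, seq.int(j, by = 9L, length.out = C)] <- block
  }
  out
}

## Adjoint of im2col: accumulate patch gradients back onto pixels.
col2imAdd <- function(G, idx, C) {
  n <- nrow(idx)
  dX <- matrix(0, n, C)
  for (j in 1:9) {
    iv <- idx[, j]
    ok <- iv > 0L
    cols <- seq.int(j, by = 9L, length.out = C)
    ## a single offset is an injective shift: no index is hit twice
    dX[iv[ok], ] <- dX[iv[ok], ] + G[ok, cols, drop = FALSE]
  }
  dX
}

## s-fold average pooling matrix (h x H) and bilinear upsampling (H x h),
## aligned on pixel centers.
poolMat <- function(H, s) {
  h <- H %/% s
  M <- matrix(0, h, H)
  for (i in seq_len(h)) M[i, (i - 1L) * s + seq_len(s)] <- 1 / s
  M
}

upMat <- function(H, s) {
  h <- H %/% s
  U <- matrix(0, H, h)
  for (r in seq_len(H)) {
    src <- (r - 0.5) / s + 0.5          # in low-res pixel units
    lo <- max(1L, min(h, as.integer(floor(src))))
    hi <- max(1L, min(h, lo + 1L))
    frac <- src - lo
    if (frac < 0) frac <- 0
    if (frac > 1) frac <- 1
    U[r, lo] <- U[r, lo] + (1 - frac)
    U[r, hi] <- U[r, hi] + frac
  }
  U
}

geom <- function(H, W, s) {
  key <- paste0("g:", H, "x", W, "x", s)
  if (!is.null(.geomCache[[key]])) return(.geomCache[[key]])
  h <- H %/% s
  w <- W %/% s
  g <- list(H = H, W = W, h = h, w = w, s = s,
            idxFull = convIdx(H, W), idxLow = convIdx(h, w),
            Ph = poolMat(H, s), Pw = poolMat(W, s),
            Uh = upMat(H, s), Uw = upMat(W, s))
  .geomCache[[key]] <- g
  g
}

## apply a separable linear resampling (rows: Mh, cols: Mw) per channel
resampleLR <- function(X, H, W, Mh, Mw) {
  C <- ncol(X)
  nOut <- nrow(Mh) * nrow(Mw)
  out <- matrix(0, nOut, C)
  for (c in seq_len(C)) {
    out[, c] <- as.vector(Mh %*% matrix(X[, c], H, W) %*% t(Mw))
  }
  out
}

heInit <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

## default architecture of the toy model
toyArch <- function(C1 = 8L, D = 16L, P = 8L, Hc = 16L, scale = 4L,
                    promptSigma = 8) {
  list(C1 = as.integer(C1), D = as.integer(D), P = as.integer(P),
       Hc = as.integer(Hc), scale = as.integer(scale),
       promptSigma = promptSigma)
}

toyInitWeights <- function(arch, seed = 42L) {
  withSeed(seed, {
    w <- new.env(parent = emptyenv())
    w$W1 <- heInit(9L * 3L, arch$C1);        w$b1 <- numeric(arch$C1)
    w$W2 <- heInit(9L * arch$C1, arch$D);    w$b2 <- numeric(arch$D)
    w$Wp <- heInit(4L, arch$P);              w$bp <- numeric(arch$P)
    w$W3 <- heInit(9L * (arch$D + arch$P), arch$Hc)
    w$b3 <- numeric(arch$Hc)
    w$W4 <- heInit(arch$Hc, 4L) * 0.1;       w$b4 <- numeric(4L)
    w$W5 <- heInit(arch$C1, 4L) * 0.1        # full-res skip into the logits
    w$Wi <- heInit(arch$Hc, 4L) * 0.1;       w$bi <- numeric(4L)
    w$Wa <- heInit(9L * arch$D, arch$Hc);    w$ba <- numeric(arch$Hc)
    w$Wo <- heInit(arch$Hc, 3L) * 0.1;       w$bo <- numeric(3L)
    w$Ws <- heInit(arch$C1, 3L) * 0.1        # full-res skip, AIS head
    w
  })
}

paramGroups <- list(
  encoder = c("W1", "b1", "W2", "b2"),
  prompt_encoder = c("Wp", "bp"),
  mask_decoder = c("W3", "b3", "W4", "b4", "W5", "Wi", "bi"),
  ais_decoder = c("Wa", "ba", "Wo", "bo", "Ws")
)

zeroGrads <- function(w) {
  g <- new.env(parent = emptyenv())
  for (nm in ls(w)) g[[nm]] <- w[[nm]] * 0
  g
}

## ---- encoder ---------------------------------------------------------

## image3: (H*W) x 3 matrix of a prepared, normalized, padded image
encForward <- function(w, image3, g) {
  A0 <- im2col(image3, g$idxFull)
  Z1 <- sweep(A0 %*% w$W1, 2L, w$b1, `+`)
  H1 <- relu(Z1)
  P1 <- resampleLR(H1, g$H, g$W, g$Ph, g$Pw)
  A1 <- im2col(P1, g$idxLow)
  Z2 <- sweep(A1 %*% w$W2, 2L, w$b2, `+`)
  E <- relu(Z2)
  list(A0 = A0, Z1 = Z1, H1 = H1, A1 = A1, Z2 = Z2, E = E)
}

## dH1: optional extra gradient on the full-resolution skip features
## (from the decoder heads' 1x1 skip connections)
encBackward <- function(w, cache, dE, g, grads, dH1 = NULL) {
  dZ2 <- dE * (cache$Z2 > 0)
  grads$W2 <- grads$W2 + crossprod(cache$A1, dZ2)
  grads$b2 <- grads$b2 + colSums(dZ2)
  dA1 <- dZ2 %*% t(w$W2)
  dP1 <- col2imAdd(dA1, g$idxLow, ncol(w$W1))
  dH1full <- resampleLR(dP1, g$h, g$w, t(g$Ph), t(g$Pw))
  if (!is.null(dH1)) dH1full <- dH1full + dH1
  dZ1 <- dH1full * (cache$Z1 > 0)
  grads$W1 <- grads$W1 + crossprod(cache$A0, dZ1)
  grads$b1 <- grads$b1 + colSums(dZ1)
  invisible(NULL)
}

## ---- prompt rasterization -------------------------------------------

## Prompts become four channels at embedding resolution: a Gaussian splat
## around positive points, one around negative points, the box interior,
## and the squashed mask prompt.
rasterPrompts <- function(prompts, g, sigma) {
  h <- g$h
  w <- g$w
  s <- g$s
  M <- matrix(0, h * w, 4L)
  ctrR <- rep(seq_len(h), w)    # low-res cell centers, low-res units
  ctrC <- rep(seq_len(w), each = h)
  sigE <- sigma / s
  splat <- function(ptsLow) {
    v <- numeric(h * w)
    for (i in seq_len(nrow(ptsLow))) {
      d2 <- (ctrR - ptsLow[i, 1L])^2 + (ctrC - ptsLow[i, 2L])^2
      v <- pmax(v, exp(-d2 / (2 * sigE^2)))
    }
    v
  }
  toLow <- function(p) cbind((p[, 1L] - 0.5) / s + 0.5,
                             (p[, 2L] - 0.5) / s + 0.5)
  if (nPoints(prompts) > 0L) {
    pl <- toLow(prompts@points)
    if (any(prompts@positive)) M[, 1L] <- splat(pl[prompts@positive, ,
                                                   drop = FALSE])
    if (any(!prompts@positive)) M[, 2L] <- splat(pl[!prompts@positive, ,
                                                    drop = FALSE])
  }
  if (hasBox(prompts)) {
    b <- prompts@box
    fullR <- (ctrR - 0.5) * s + 0.5
    fullC <- (ctrC - 0.5) * s + 0.5
    M[, 3L] <- as.numeric(fullR >= b[1L] - 0.5 & fullR <= b[3L] + 0.5 &
                          fullC >= b[2L] - 0.5 & fullC <= b[4L] + 0.5)
  }
  if (hasMaskPrompt(prompts)) {
    mp <- prompts@maskPrompt
    if (!identical(dim(mp), c(h, w)))
      stop("mask prompt must be at embedding resolution (", h, " x ", w, ")")
    M[, 4L] <- tanh(as.vector(mp) / 2)
  }
  M
}

## ---- mask decoder ----------------------------------------------------

## H1: full-resolution first-layer features entering the logits through a
## 1x1 skip connection — the coarse prompt-conditioned map gates the
## object, the skip restores boundary detail.
decForward <- function(w, E, M, g, H1) {
  Zp <- sweep(M %*% w$Wp, 2L, w$bp, `+`)
  Pf <- relu(Zp)
  Zc <- cbind(E, Pf)
  Ac <- im2col(Zc, g$idxLow)
  Z3 <- sweep(Ac %*% w$W3, 2L, w$b3, `+`)
  H3 <- relu(Z3)
  Llow <- sweep(H3 %*% w$W4, 2L, w$b4, `+`)
  Lfull <- resampleLR(Llow, g$h, g$w, g$Uh, g$Uw) + H1 %*% w$W5
  gbar <- colMeans(H3)
  iouLogit <- as.numeric(gbar %*% w$Wi + w$bi)
  list(M = M, Zp = Zp, Pf = Pf, Ac = Ac, Z3 = Z3, H3 = H3, H1 = H1,
       Lfull = Lfull, iouLogit = iouLogit, iouEst = sigmoid(iouLogit))
}

## dLfull: (H*W) x 4 gradient on full-res logits; dIouLogit: length-4.
## Returns list(dE, dH1); accumulates weight grads in `grads`.
decBackward <- function(w, cache, dLfull, dIouLogit, g, grads) {
  D <- nrow(w$Wa) %/% 9L   # embedding channels
  grads$W5 <- grads$W5 + crossprod(cache$H1, dLfull)
  dH1 <- dLfull %*% t(w$W5)
  dLlow <- resampleLR(dLfull, g$H, g$W, t(g$Uh), t(g$Uw))
  grads$W4 <- grads$W4 + crossprod(cache$H3, dLlow)
  grads$b4 <- grads$b4 + colSums(dLlow)
  dH3 <- dLlow %*% t(w$W4)
  if (any(dIouLogit != 0)) {
    grads$Wi <- grads$Wi + outer(colMeans(cache$H3), dIouLogit)
    grads$bi <- grads$bi + dIouLogit
    dgbar <- as.numeric(w$Wi %*% dIouLogit)
    dH3 <- dH3 + matrix(dgbar, nrow(cache$H3), length(dgbar),
                        byrow = TRUE) / nrow(cache$H3)
  }
  dZ3 <- dH3 * (cache$Z3 > 0)
  grads$W3 <- grads$W3 + crossprod(cache$Ac, dZ3)
  grads$b3 <- grads$b3 + colSums(dZ3)
  dAc <- dZ3 %*% t(w$W3)
  Ctot <- as.integer(D + ncol(w$Wp))
  dZcat <- col2imAdd(dAc, g$idxLow, Ctot)
  dE <- dZcat[, seq_len(D), drop = FALSE]
  dPf <- dZcat[, D + seq_len(ncol(w$Wp)), drop = FALSE]
  dZp <- dPf * (cache$Zp > 0)
  grads$Wp <- grads$Wp + crossprod(cache$M, dZp)
  grads$bp <- grads$bp + colSums(dZp)
  list(dE = dE, dH1 = dH1)
}

## ---- AIS decoder head ------------------------------------------------

aisForward <- function(w, E, g, H1) {
  Aa <- im2col(E, g$idxLow)
  Za <- sweep(Aa %*% w$Wa, 2L, w$ba, `+`)
  Ha <- relu(Za)
  Olow <- sweep(Ha %*% w$Wo, 2L, w$bo, `+`)
  Ofull <- resampleLR(Olow, g$h, g$w, g$Uh, g$Uw) + H1 %*% w$Ws
  list(Aa = Aa, Za = Za, Ha = Ha, H1 = H1, Ofull = Ofull,
       probs = sigmoid(Ofull))
}

## returns list(dE, dH1); accumulates weight grads in `grads`
aisBackward <- function(w, cache, dOfull, g, grads) {
  grads$Ws <- grads$Ws + crossprod(cache$H1, dOfull)
  dH1 <- dOfull %*% t(w$Ws)
  dOlow <- resampleLR(dOfull, g$H, g$W, t(g$Uh), t(g$Uw))
  grads$Wo <- grads$Wo + crossprod(cache$Ha, dOlow)
  grads$bo <- grads$bo + colSums(dOlow)
  dHa <- dOlow %*% t(w$Wo)
  dZa <- dHa * (cache$Za > 0)
  grads$Wa <- grads$Wa + crossprod(cache$Aa, dZa)
  grads$ba <- grads$ba + colSums(dZa)
  D <- nrow(w$Wa) / 9L
  list(dE = col2imAdd(dZa %*% t(w$Wa), g$idxLow, as.integer(D)),
       dH1 = dH1)
}

## ---- Adam ------------------------------------------------------------

adamInit <- function(w) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(setNames(ls(w), ls(w)), function(nm) w[[nm]] * 0)
  st$v <- st$m
  st
}

adamStep <- function(w, grads, st, lr, frozen = character(),
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  skip <- unlist(paramGroups[frozen], use.names = FALSE)
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in ls(w)) {
    if (nm %in% skip) next
    gmat <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gmat
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gmat^2
    w[[nm]] <- w[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  invisible(NULL)
}
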