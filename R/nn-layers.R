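# Internal neural primitives: linear, layer norm, multi-head
# self-attention, position-wise feed-forward, and the post-norm
# Transformer block, each as a forward returning a cache plus a matching
# backward. Gradients are hand-derived; the finite-difference tests in
# the suite pin them down.

linFwd <- function(X, W, b) {
  list(out = addRowVec(X %*% W, b), X = X, W = W)
}

linBwd <- function(cache, dOut) {
  list(dX = tcrossprod(dOut, cache$W),
       dW = crossprod(cache$X, dOut),
       db = colSums(dOut))
}

# Row-wise layer normalisation without learnable affine parameters.
lnFwd <- function(X, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  s <- sqrt(rowMeans(Xc^2) + eps)
  list(out = Xc / s, s = s)
}

lnBwd <- function(cache, dY) {
  Y <- cache$out
  (dY - rowMeans(dY) - Y * rowMeans(dY * Y)) / cache$s
}

# Multi-head scaled dot-product self-attention.
# w: list(Wq, Wk, Wv, Wo [d x d], bo [d])
mhsaFwd <- function(X, w, nHeads) {
  d <- ncol(X)
  if (d %% nHeads != 0L) {
    stop(sprintf("d_model (%d) not divisible by n_heads (%d)", d, nHeads),
         call. = FALSE)
  }
  dh <- d %/% nHeads
  Q <- X %*% w$Wq; K <- X %*% w$Wk; V <- X %*% w$Wv
  A <- vector("list", nHeads)
  Hcat <- matrix(0, nrow(X), d)
  for (h in seq_len(nHeads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmaxRows(S)
    Hcat[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  list(out = addRowVec(Hcat %*% w$Wo, w$bo),
       X = X, Q = Q, K = K, V = V, A = A, Hcat = Hcat,
       nHeads = nHeads, dh = dh, w = w)
}

mhsaBwd <- function(cache, dOut) {
  w <- cache$w
  dh <- cache$dh
  dHcat <- tcrossprod(dOut, w$Wo)
  dW <- list(Wo = crossprod(cache$Hcat, dOut), bo = colSums(dOut))
  dQ <- matrix(0, nrow(cache$X), ncol(cache$X))
  dK <- dQ; dV <- dQ
  for (h in seq_len(cache$nHeads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dH <- dHcat[, idx, drop = FALSE]
    dA <- tcrossprod(dH, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dH)
    # softmax backward, row-wise
    dS <- (dA - rowSums(dA * A)) * A
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  dW$Wq <- crossprod(cache$X, dQ)
  dW$Wk <- crossprod(cache$X, dK)
  dW$Wv <- crossprod(cache$X, dV)
  dX <- tcrossprod(dQ, w$Wq) + tcrossprod(dK, w$Wk) + tcrossprod(dV, w$Wv)
  list(dX = dX, dW = dW)
}

# Position-wise feed-forward: linear -> ReLU -> linear.
ffnFwd <- function(X, w) {
  l1 <- linFwd(X, w$W1, w$b1)
  H <- pmax(l1$out, 0)
  l2 <- linFwd(H, w$W2, w$b2)
  list(out = l2$out, l1 = l1, H = H, l2 = l2)
}

ffnBwd <- function(cache, dOut) {
  g2 <- linBwd(cache$l2, dOut)
  dH <- g2$dX * (cache$H > 0)
  g1 <- linBwd(cache$l1, dH)
  list(dX = g1$dX,
       dW = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db))
}

# Post-norm Transformer block:
#   N1 = LN(X + MHSA(X));  N2 = LN(N1 + FFN(N1))
# Inverted dropout on the two sublayer outputs when training with
# dropout > 0; masks are cached for the backward pass.
blockFwd <- function(X, w, nHeads, dropout = 0, training = FALSE) {
  useDrop <- training && dropout > 0
  att <- mhsaFwd(X, w$att, nHeads)
  aOut <- att$out
  mA <- NULL
  if (useDrop) {
    mA <- matrix(stats::rbinom(length(aOut), 1L, 1 - dropout), nrow(aOut)) /
      (1 - dropout)
    aOut <- aOut * mA
  }
  n1 <- lnFwd(X + aOut)
  ffn <- ffnFwd(n1$out, w$ffn)
  fOut <- ffn$out
  mF <- NULL
  if (useDrop) {
    mF <- matrix(stats::rbinom(length(fOut), 1L, 1 - dropout), nrow(fOut)) /
      (1 - dropout)
    fOut <- fOut * mF
  }
  n2 <- lnFwd(n1$out + fOut)
  list(out = n2$out, att = att, n1 = n1, ffn = ffn, n2 = n2,
       mA = mA, mF = mF)
}

blockBwd <- function(cache, dOut) {
  dR2 <- lnBwd(cache$n2, dOut)
  dF <- if (is.null(cache$mF)) dR2 else dR2 * cache$mF
  gF <- ffnBwd(cache$ffn, dF)
  dN1 <- dR2 + gF$dX
  dR1 <- lnBwd(cache$n1, dN1)
  dA <- if (is.null(cache$mA)) dR1 else dR1 * cache$mA
  gA <- mhsaBwd(cache$att, dA)
  list(dX = dR1 + gA$dX, dAtt = gA$dW, dFfn = gF$dW)
}

# Seeded uniform init scaled by 1/sqrt(fan_in).
initMat <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
}

initBlockWeights <- function(d, dFf) {
  list(att = list(Wq = initMat(d, d), Wk = initMat(d, d),
                  Wv = initMat(d, d), Wo = initMat(d, d),
                  bo = numeric(d)),
       ffn = list(W1 = initMat(d, dFf), b1 = numeric(dFf),
                  W2 = initMat(dFf, d), b2 = numeric(d)))
}

# Flatten nested weight/grad lists to a flat named list for SGD.
flattenWeights <- function(w, prefix = "") {
  out <- list()
  for (nm in names(w)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(w[[nm]])) out <- c(out, flattenWeights(w[[nm]], key))
    else out[[key]] <- w[[nm]]
  }
  out
}

unflattenWeights <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- .assignPath(out, parts, flat[[key]])
  }
  out
}

.assignPath <- function(lst, parts, value) {
  if (length(parts) == 1L) {
    lst[[parts]] <- value
  } else {
    if (is.null(lst[[parts[1]]])) lst[[parts[1]]] <- list()
    lst[[parts[1]]] <- .assignPath(lst[[parts[1]]], parts[-1], value)
  }
  lst
}

# Accumulation of two structurally identical grad lists; every list in
# a weight/grad bundle is named, so matching is by name.
accumGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) accumGrads(a[[nm]], b[[nm]])
               else a[[nm]] + b[[nm]]
  }
  a
}

scaleGrads <- function(g, s) {
  lapply(g, function(x) if (is.list(x)) scaleGrads(x, s) else x * s)
}

zeroLike <- function(w) {
  lapply(w, function(x) if (is.list(x)) zeroLike(x) else x * 0)
}

# Feature standardisation (z-score) used between the frozen joint
# features and the MLP; works on a vector or a row-matrix of features.
applyScaler <- function(j, scaler) {
  if (is.null(scaler)) return(j)
  if (is.matrix(j)) {
    addRowVec(j, -scaler$mu) / rep(scaler$sigma, each = nrow(j))
  } else {
    (j - scaler$mu) / scaler$sigma
  }
}

# SGD with weight decay: w <- w - lr (g + wd w).
sgdStep <- function(w, g, lr, weightDecay = 0) {
  for (nm in names(w)) {
    if (is.null(g[[nm]])) next
    if (is.list(w[[nm]])) {
      w[[nm]] <- sgdStep(w[[nm]], g[[nm]], lr, weightDecay)
    } else {
      w[[nm]] <- w[[nm]] - lr * (g[[nm]] + weightDecay * w[[nm]])
    }
  }
  w
}
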