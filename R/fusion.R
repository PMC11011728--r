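# Multimodal projection head, joint-representation fusion, and the MLP
# softmax phase classifier.

#' Initialise a projection head
#'
#' The head is a two-stage map: a feed-forward network (two fully
#' connected layers with a ReLU between them) followed by a final
#' linear layer to the configured joint-input size.
#'
#' @param dIn input width (encoder pooled width).
#' @param dHidden feed-forward hidden width (default \code{dIn}).
#' @param dOut joint-input width (default \code{dIn}).
#' @param seed integer seed.
#' @return weight list (W1, b1, W2, b2, W3, b3).
#' @export
initProjectionHead <- function(dIn, dHidden = dIn, dOut = dIn, seed = 1L) {
  withSeed(seed, {
    list(W1 = initMat(dIn, dHidden), b1 = numeric(dHidden),
         W2 = initMat(dHidden, dIn), b2 = numeric(dIn),
         W3 = initMat(dIn, dOut), b3 = numeric(dOut))
  })
}

headFwd <- function(h, w) {
  X <- matrix(h, 1L)
  l1 <- linFwd(X, w$W1, w$b1)
  H <- pmax(l1$out, 0)
  l2 <- linFwd(H, w$W2, w$b2)
  l3 <- linFwd(l2$out, w$W3, w$b3)
  list(out = drop(l3$out), l1 = l1, H = H, l2 = l2, l3 = l3)
}

headBwd <- function(cache, dOut) {
  g3 <- linBwd(cache$l3, matrix(dOut, 1L))
  g2 <- linBwd(cache$l2, g3$dX)
  dH <- g2$dX * (cache$H > 0)
  g1 <- linBwd(cache$l1, dH)
  list(dIn = drop(g1$dX),
       dW = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                 W3 = g3$dW, b3 = g3$db))
}

#' Apply a projection head
#'
#' linear -> ReLU -> linear (the feed-forward network), then a final
#' linear map into the joint space.
#'
#' @param h encoder pooled vector.
#' @param weights output of \code{\link{initProjectionHead}} (or trained).
#' @return projected numeric vector.
#' @export
projectionHead <- function(h, weights) {
  if (length(h) != nrow(weights$W1)) {
    stop(sprintf("input length %d does not match head input %d",
                 length(h), nrow(weights$W1)), call. = FALSE)
  }
  headFwd(h, weights)$out
}

#' Combine projected modality vectors into the joint representation
#'
#' Concatenation, image part first; order is significant.
#'
#' @param hImg projected image vector.
#' @param hTxt projected text vector.
#' @return numeric vector of length \code{length(hImg) + length(hTxt)}.
#' @export
combineJoint <- function(hImg, hTxt) {
  stopIfNotFinite(hImg, "image projection")
  stopIfNotFinite(hTxt, "text projection")
  c(hImg, hTxt)
}

#' Initialise the MLP phase classifier
#'
#' One hidden ReLU layer (default width 128) then a linear map to 7
#' phase logits.
#'
#' @param dIn joint-representation length.
#' @param dHidden hidden width (default 128).
#' @param nClasses number of phases (default 7).
#' @param seed integer seed.
#' @return weight list (Wh, bh, Wo, bo).
#' @export
initMlp <- function(dIn, dHidden = 128L, nClasses = 7L, seed = 1L) {
  withSeed(seed, {
    list(Wh = initMat(dIn, dHidden), bh = numeric(dHidden),
         Wo = initMat(dHidden, nClasses), bo = numeric(nClasses))
  })
}

mlpFwd <- function(j, w) {
  X <- matrix(j, 1L)
  l1 <- linFwd(X, w$Wh, w$bh)
  H <- pmax(l1$out, 0)
  l2 <- linFwd(H, w$Wo, w$bo)
  logits <- drop(l2$out)
  list(logits = logits, probs = softmaxVec(logits), l1 = l1, H = H, l2 = l2)
}

# Backward from dLogits (softmax+CE gradient formed by the caller).
mlpBwd <- function(cache, dLogits) {
  g2 <- linBwd(cache$l2, matrix(dLogits, 1L))
  dH <- g2$dX * (cache$H > 0)
  g1 <- linBwd(cache$l1, dH)
  list(dIn = drop(g1$dX),
       dW = list(Wh = g1$dW, bh = g1$db, Wo = g2$dW, bo = g2$db))
}

#' MLP forward pass: phase probabilities and prediction
#'
#' Hidden ReLU layer(s) then linear logits and softmax over the 7
#' phases. Ties in the argmax break toward the lowest class index.
#'
#' @param j joint representation vector.
#' @param weights output of \code{\link{initMlp}} (or trained).
#' @return list with \code{probabilities} (7-simplex vector) and
#'   \code{predictedPhase} (integer 0..6).
#' @export
mlpForward <- function(j, weights) {
  if (length(j) != nrow(weights$Wh)) {
    stop(sprintf("input length %d does not match MLP input %d",
                 length(j), nrow(weights$Wh)), call. = FALSE)
  }
  f <- mlpFwd(j, weights)
  list(probabilities = f$probs,
       predictedPhase = which.max(f$probs) - 1L)
}
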