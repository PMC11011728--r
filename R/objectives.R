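# Objectives and schedules: multimodal contrastive (InfoNCE) loss, NCE
# loss, cross-entropy, cosine similarity, and the warmup + cosine
# annealed learning-rate schedule.

#' Cosine similarity
#'
#' @param a,b non-zero numeric vectors of equal length.
#' @return \code{dot(a, b) / (||a|| ||b||)}, in [-1, 1].
#' @export
cosineSimilarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

# Pairwise cosine similarity matrix between rows of X and rows of Y.
.cosineMatrix <- function(X, Y) {
  nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
  if (any(nx == 0) || any(ny == 0)) {
    stop("zero-norm row in contrastive batch", call. = FALSE)
  }
  tcrossprod(X, Y) / outer(nx, ny)
}

#' Multimodal contrastive (InfoNCE) loss
#'
#' \deqn{L = -\frac{1}{n}\sum_i \log\frac{\exp(sim(x_i, y_i)/\tau)}
#'   {\sum_j \exp(sim(x_i, y_j)/\tau)}}
#' where \eqn{sim} is cosine similarity and \eqn{\tau} the temperature.
#' The denominator runs over all in-batch texts \eqn{y_j} (in-batch
#' negatives). With \code{symmetric = TRUE} the text-to-image direction
#' is averaged in. Computed with a numerically stable log-sum-exp.
#'
#' @param X n x d image-side projections (rows \eqn{x_i}).
#' @param Y n x d text-side projections (rows \eqn{y_i}).
#' @param tau temperature (> 0; default 0.1).
#' @param symmetric average the two directions (default FALSE, the
#'   image-to-text direction only).
#' @return non-negative scalar loss.
#' @export
multimodalContrastiveLoss <- function(X, Y, tau = 0.1, symmetric = FALSE) {
  contrastiveLossGrad(X, Y, tau = tau, symmetric = symmetric,
                      withGrad = FALSE)$loss
}

#' Contrastive loss with analytic gradients
#'
#' As \code{\link{multimodalContrastiveLoss}}, additionally returning
#' the gradients of the loss with respect to X and Y (used by the SGD
#' training loop; checked against finite differences in the test
#' suite).
#'
#' @inheritParams multimodalContrastiveLoss
#' @param withGrad compute gradients (default TRUE).
#' @return list with \code{loss}, and if requested \code{dX}, \code{dY}.
#' @export
contrastiveLossGrad <- function(X, Y, tau = 0.1, symmetric = FALSE,
                                withGrad = TRUE) {
  stopifnot(is.matrix(X), is.matrix(Y), all(dim(X) == dim(Y)), tau > 0)
  stopIfNotFinite(X, "X"); stopIfNotFinite(Y, "Y")
  n <- nrow(X)
  S <- .cosineMatrix(X, Y)
  Z <- S / tau
  m <- apply(Z, 1L, max)
  lse <- m + log(rowSums(exp(Z - m)))
  loss <- -mean(diag(Z) - lse)
  dS <- NULL
  if (withGrad || symmetric) {
    P <- exp(Z - lse)                       # row-wise softmax
    dS <- (P - diag(n)) / (n * tau)         # dL/dS, image->text direction
  }
  if (symmetric) {
    Zc <- Z
    mc <- apply(Zc, 2L, max)
    lsec <- mc + log(colSums(exp(sweep(Zc, 2L, mc))))
    lossT <- -mean(diag(Zc) - lsec)
    if (withGrad) {
      Pc <- exp(sweep(Zc, 2L, lsec))        # column-wise softmax
      dSc <- (Pc - diag(n)) / (n * tau)
      dS <- (dS + dSc) / 2
    }
    loss <- (loss + lossT) / 2
  }
  out <- list(loss = loss)
  if (withGrad) {
    nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
    Xh <- X / nx; Yh <- Y / ny
    # dS_ij/dx_i = (yhat_j - S_ij xhat_i)/||x_i||
    dX <- (dS %*% Yh - rowSums(dS * S) * Xh) / nx
    dY <- (t(dS) %*% Xh - colSums(dS * S) * Yh) / ny
    out$dX <- dX
    out$dY <- dY
  }
  out
}

#' Noise contrastive estimation loss
#'
#' \deqn{L = -\frac{1}{n}\sum_i \log\frac{p(x_i)}{p(x_i) + k\,p_n(x_i)}}
#' with model densities \eqn{p}, noise densities \eqn{p_n}, and \eqn{k}
#' noise samples per true sample.
#'
#' @param pTrue numeric vector of model densities (>= 0).
#' @param pNoise numeric vector of noise densities (>= 0), same length.
#' @param k noise samples per true sample (>= 1).
#' @return non-negative scalar loss.
#' @export
nceLoss <- function(pTrue, pNoise, k = 1L) {
  stopifnot(length(pTrue) == length(pNoise), k >= 1,
            all(pTrue >= 0), all(pNoise >= 0))
  denom <- pTrue + k * pNoise
  if (any(denom == 0)) {
    stop("degenerate NCE input: p + k*pn is zero for some sample",
         call. = FALSE)
  }
  -mean(log(pTrue / denom))
}

#' Cross-entropy of a probability vector at a label
#'
#' \code{-log(probabilities[label])}, floored at \code{eps} to avoid
#' infinite loss on hard zeros.
#'
#' @param probabilities simplex vector (sums to 1 within 1e-8).
#' @param label class index, 0-based (matching phase ids).
#' @param eps probability floor (default 1e-12).
#' @return non-negative scalar.
#' @export
crossEntropy <- function(probabilities, label, eps = 1e-12) {
  if (abs(sum(probabilities) - 1) > 1e-8) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  idx <- as.integer(label) + 1L
  if (idx < 1L || idx > length(probabilities)) {
    stop(sprintf("label %s out of range", label), call. = FALSE)
  }
  -log(max(probabilities[idx], eps))
}

#' Warmup + cosine annealed learning-rate schedule
#'
#' Linear ramp from 0 to \code{baseLr} over the warmup steps, then
#' \code{floorLr + (baseLr - floorLr) * (1 + cos(pi * progress)) / 2}
#' over the remaining steps (the published schedule: 5 warmup epochs,
#' cosine decay).
#'
#' @param step current step (0-based, <= total steps).
#' @param baseLr peak learning rate (published value 0.001).
#' @param warmupEpochs warmup length in epochs (published value 5).
#' @param totalEpochs total training epochs.
#' @param stepsPerEpoch optimiser steps per epoch.
#' @param floorLr final learning rate (default 0).
#' @return learning rate at \code{step}.
#' @export
lrSchedule <- function(step, baseLr = 0.001, warmupEpochs = 5L,
                       totalEpochs = 50L, stepsPerEpoch = 1L, floorLr = 0) {
  stopifnot(warmupEpochs < totalEpochs, step >= 0)
  warm <- warmupEpochs * stepsPerEpoch
  total <- totalEpochs * stepsPerEpoch
  if (step < warm) return(baseLr * step / warm)
  progress <- (step - warm) / max(total - warm, 1L)
  progress <- min(progress, 1)
  floorLr + (baseLr - floorLr) * 0.5 * (1 + cos(pi * progress))
}
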