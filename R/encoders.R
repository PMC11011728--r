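# Modality-specific Transformer encoders (self-attention + positional
# encoding), plus the single-encoder ablation forward.

#' Encoder configuration
#'
#' @param nLayers number of Transformer blocks (published setting 12;
#'   desk preset 2).
#' @param dModel model width; must be even and divisible by nHeads.
#' @param nHeads attention heads.
#' @param dFf feed-forward hidden width.
#' @param dropout dropout rate in [0, 1); active only during training.
#' @param seed integer seed for weight initialisation.
#' @return a validated list of class \code{"EncoderConfig"}.
#' @export
encoderConfig <- function(nLayers = 2L, dModel = 32L, nHeads = 4L,
                          dFf = 64L, dropout = 0, seed = 1L) {
  stopifnot(nLayers >= 1L, dModel %% nHeads == 0L, dModel %% 2L == 0L,
            dropout >= 0, dropout < 1)
  structure(list(nLayers = as.integer(nLayers), dModel = as.integer(dModel),
                 nHeads = as.integer(nHeads), dFf = as.integer(dFf),
                 dropout = dropout, seed = as.integer(seed)),
            class = "EncoderConfig")
}

#' Sinusoidal positional encoding
#'
#' \code{PE[pos, 2i] = sin(pos / 10000^(2i/d))},
#' \code{PE[pos, 2i+1] = cos(pos / 10000^(2i/d))}, positions 0-based.
#'
#' @param L sequence length (>= 1).
#' @param dModel even embedding dimension.
#' @return an L x dModel matrix with entries in [-1, 1].
#' @export
positionalEncoding <- function(L, dModel) {
  stopifnot(L >= 1L)
  if (dModel %% 2L != 0L) stop("dModel must be even", call. = FALSE)
  key <- paste0(L, "x", dModel)
  hit <- .peCache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- seq_len(L) - 1L
  i <- seq_len(dModel %/% 2L) - 1L
  angle <- outer(pos, 1 / 10000^(2 * i / dModel))
  PE <- matrix(0, L, dModel)
  PE[, 2 * i + 1L] <- sin(angle)
  PE[, 2 * i + 2L] <- cos(angle)
  .peCache[[key]] <- PE
  PE
}

# Memo for positional encodings (pure function of L and dModel).
.peCache <- new.env(parent = emptyenv())

#' Multi-head self-attention
#'
#' Per head, \code{softmax(Q K' / sqrt(d_head)) V} with learned Q, K, V
#' projections; heads are concatenated and output-projected.
#'
#' @param X L x d input matrix.
#' @param weights list with entries Wq, Wk, Wv, Wo (d x d) and bo (d).
#' @param nHeads number of heads; d must be divisible by it.
#' @param returnAttention if TRUE, attach the per-head attention
#'   matrices as attribute \code{"attention"}.
#' @return L x d output matrix.
#' @export
multiHeadSelfAttention <- function(X, weights, nHeads = 1L,
                                   returnAttention = FALSE) {
  cache <- mhsaFwd(X, weights, nHeads)
  out <- cache$out
  if (returnAttention) attr(out, "attention") <- cache$A
  out
}

#' Initialise encoder weights
#'
#' Seeded uniform initialisation scaled by 1/sqrt(fan_in).
#'
#' @param config an \code{\link{encoderConfig}}.
#' @return nested list of per-block weights.
#' @export
initEncoderWeights <- function(config) {
  withSeed(config$seed, {
    blocks <- lapply(seq_len(config$nLayers), function(i) {
      initBlockWeights(config$dModel, config$dFf)
    })
    names(blocks) <- paste0("b", seq_along(blocks))
    blocks
  })
}

# Forward through the encoder stack with caches (internal training path).
encFwd <- function(X, blocks, config, training = FALSE) {
  stopIfNotFinite(X, "encoder input")
  X <- X + positionalEncoding(nrow(X), ncol(X))
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    caches[[i]] <- blockFwd(X, blocks[[i]], config$nHeads,
                            dropout = config$dropout, training = training)
    X <- caches[[i]]$out
  }
  list(hidden = X, pooled = colMeans(X), caches = caches)
}

# Backward through the stack. dHidden and/or dPooled may be NULL.
encBwd <- function(fwd, blocks, dHidden = NULL, dPooled = NULL) {
  H <- fwd$hidden
  dX <- if (is.null(dHidden)) matrix(0, nrow(H), ncol(H)) else dHidden
  if (!is.null(dPooled)) {
    dX <- dX + matrix(dPooled / nrow(H), nrow(H), ncol(H), byrow = TRUE)
  }
  dBlocks <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    g <- blockBwd(fwd$caches[[i]], dX)
    dX <- g$dX
    dBlocks[[i]] <- list(att = g$dAtt, ffn = g$dFfn)
  }
  names(dBlocks) <- names(blocks)
  list(dX = dX, dBlocks = dBlocks)
}

#' Encode an embedding sequence
#'
#' Adds sinusoidal positional encoding, then applies \code{nLayers}
#' post-norm Transformer blocks (self-attention + residual + layer norm,
#' feed-forward + residual + layer norm). The pooled output is the mean
#' over positions of the final hidden states.
#'
#' @param seq L x dModel embedding matrix.
#' @param config an \code{\link{encoderConfig}}.
#' @param weights output of \code{\link{initEncoderWeights}} (or trained).
#' @param training logical; enables dropout if configured.
#' @return list with elements \code{hidden} (L x dModel) and
#'   \code{pooled} (dModel), of class \code{"EncoderOutput"}.
#' @export
encodeSequence <- function(seq, config, weights, training = FALSE) {
  if (ncol(seq) != config$dModel) {
    stop(sprintf("sequence dimension %d does not match dModel %d",
                 ncol(seq), config$dModel), call. = FALSE)
  }
  fwd <- encFwd(seq, weights, config, training = training)
  structure(list(hidden = fwd$hidden, pooled = fwd$pooled),
            class = "EncoderOutput")
}

#' Single-encoder ablation forward
#'
#' Concatenates the image and text embedding sequences along the
#' sequence axis (image positions first) and encodes them with one
#' shared Transformer encoder; returns the pooled vector.
#'
#' @param imgSeq L_img x d image embedding sequence.
#' @param txtSeq L_txt x d text embedding sequence (same d).
#' @param config an \code{\link{encoderConfig}}.
#' @param weights encoder weights.
#' @return pooled numeric vector of length dModel.
#' @export
singleTowerForward <- function(imgSeq, txtSeq, config, weights) {
  if (ncol(imgSeq) != ncol(txtSeq)) {
    stop(sprintf("modality dimensions differ: %d vs %d",
                 ncol(imgSeq), ncol(txtSeq)), call. = FALSE)
  }
  encodeSequence(rbind(imgSeq, txtSeq), config, weights)$pooled
}
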