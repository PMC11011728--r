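# Modality towers: a ViT-style image tower (patchify -> linear
# projection -> Transformer blocks -> global average pooling) and a
# token-embedding text tower, plus an import path for externally
# precomputed embeddings (e.g. from a pretrained ViT/BERT).

#' Tower configuration
#'
#' The published setting uses a ViT-B/16-style tower with output width
#' 768; the desk preset shrinks the width to 32 and the depth to one
#' block so the full pipeline trains on a CPU in seconds.
#'
#' @param dOut output embedding width (768 published; 32 desk preset).
#' @param patchSize square patch side in pixels (default 16).
#' @param nBlocks Transformer blocks inside the tower (0 = linear
#'   patch projection only).
#' @param nHeads,dFf block sizes.
#' @param usePositional add sinusoidal positional encoding to the
#'   projected patch/token sequence (default TRUE).
#' @param vocabSize text vocabulary size (text tower; set by
#'   \code{\link{initTextTower}} from the vocabulary).
#' @param seed integer seed for weight initialisation.
#' @return a validated list of class \code{"TowerConfig"}.
#' @export
towerConfig <- function(dOut = 32L, patchSize = 16L, nBlocks = 1L,
                        nHeads = 4L, dFf = 64L, usePositional = TRUE,
                        vocabSize = NA_integer_, seed = 1L) {
  stopifnot(dOut %% nHeads == 0L, dOut %% 2L == 0L, patchSize >= 1L,
            nBlocks >= 0L)
  structure(list(dOut = as.integer(dOut), patchSize = as.integer(patchSize),
                 nBlocks = as.integer(nBlocks), nHeads = as.integer(nHeads),
                 dFf = as.integer(dFf), usePositional = usePositional,
                 vocabSize = as.integer(vocabSize), seed = as.integer(seed)),
            class = "TowerConfig")
}

#' Cut a frame into flattened patches
#'
#' Splits an H x W x C frame into non-overlapping P x P patches in
#' row-major order (left to right, top to bottom) and flattens each to a
#' vector of length P*P*C. The concatenation of all patch vectors is a
#' permutation of the input pixels.
#'
#' @param frame H x W x C numeric array (or H x W matrix).
#' @param patchSize patch side P; H and W must be divisible by it.
#' @return an (H/P)(W/P) x (P*P*C) matrix.
#' @export
patchify <- function(frame, patchSize) {
  P <- as.integer(patchSize)
  d <- dim(frame)
  if (length(d) == 2L) frame <- array(frame, dim = c(d, 1L))
  d <- dim(frame)
  if (d[1] %% P != 0L) {
    stop(sprintf("frame height %d not divisible by patch size %d", d[1], P),
         call. = FALSE)
  }
  if (d[2] %% P != 0L) {
    stop(sprintf("frame width %d not divisible by patch size %d", d[2], P),
         call. = FALSE)
  }
  nh <- d[1] %/% P; nw <- d[2] %/% P
  out <- matrix(0, nh * nw, P * P * d[3])
  k <- 0L
  for (i in seq_len(nh)) {
    for (j in seq_len(nw)) {
      k <- k + 1L
      out[k, ] <- as.vector(frame[((i - 1L) * P + 1L):(i * P),
                                  ((j - 1L) * P + 1L):(j * P), , drop = FALSE])
    }
  }
  out
}

#' Reassemble a frame from its patches
#'
#' Inverse of \code{\link{patchify}}.
#'
#' @param patches matrix produced by \code{\link{patchify}}.
#' @param H,W,C original frame dimensions.
#' @param patchSize patch side used to cut the frame.
#' @return an H x W x C array.
#' @export
unpatchify <- function(patches, H, W, C, patchSize) {
  P <- as.integer(patchSize)
  nh <- H %/% P; nw <- W %/% P
  frame <- array(0, dim = c(H, W, C))
  k <- 0L
  for (i in seq_len(nh)) {
    for (j in seq_len(nw)) {
      k <- k + 1L
      frame[((i - 1L) * P + 1L):(i * P),
            ((j - 1L) * P + 1L):(j * P), ] <- array(patches[k, ],
                                                    dim = c(P, P, C))
    }
  }
  frame
}

#' Initialise the image tower
#'
#' @param config a \code{\link{towerConfig}}; \code{frameSize} fixes the
#'   patch-vector length.
#' @param frameSize frame side in pixels (frames are square, 3 channels).
#' @return nested weight list: \code{proj} (linear patch projection) and
#'   \code{blocks}.
#' @export
initImageTower <- function(config, frameSize = 64L) {
  dPatch <- config$patchSize^2 * 3L
  withSeed(config$seed, {
    blocks <- lapply(seq_len(config$nBlocks), function(i) {
      initBlockWeights(config$dOut, config$dFf)
    })
    names(blocks) <- if (length(blocks)) paste0("b", seq_along(blocks))
    list(proj = list(W = initMat(dPatch, config$dOut),
                     b = numeric(config$dOut)),
         blocks = blocks)
  })
}

# Image tower forward with caches: patchify -> linear -> (+PE) -> blocks.
imageTowerFwd <- function(patches, weights, config) {
  lin <- linFwd(patches, weights$proj$W, weights$proj$b)
  X <- lin$out
  if (isTRUE(config$usePositional)) {
    X <- X + positionalEncoding(nrow(X), ncol(X))
  }
  caches <- vector("list", length(weights$blocks))
  for (i in seq_along(weights$blocks)) {
    caches[[i]] <- blockFwd(X, weights$blocks[[i]], config$nHeads)
    X <- caches[[i]]$out
  }
  list(seq = X, pooled = colMeans(X), lin = lin, caches = caches)
}

imageTowerBwd <- function(fwd, weights, dSeq) {
  dX <- dSeq
  dBlocks <- vector("list", length(weights$blocks))
  for (i in rev(seq_along(weights$blocks))) {
    g <- blockBwd(fwd$caches[[i]], dX)
    dX <- g$dX
    dBlocks[[i]] <- list(att = g$dAtt, ffn = g$dFfn)
  }
  names(dBlocks) <- names(weights$blocks)
  gl <- linBwd(fwd$lin, dX)
  list(dW = list(proj = list(W = gl$dW, b = gl$db), blocks = dBlocks))
}

#' Embed one frame
#'
#' Full image-tower forward: patchify, linear projection, positional
#' encoding (if configured), Transformer blocks, then global average
#' pooling over patch positions.
#'
#' @param frame H x W x 3 array; H and W divisible by the patch size.
#' @param config a \code{\link{towerConfig}}.
#' @param weights output of \code{\link{initImageTower}} (or trained).
#' @return numeric vector of length \code{dOut}.
#' @export
embedImage <- function(frame, config, weights) {
  patches <- patchify(frame, config$patchSize)
  if (ncol(patches) != nrow(weights$proj$W)) {
    stop(sprintf("patch vector length %d does not match projection rows %d",
                 ncol(patches), nrow(weights$proj$W)), call. = FALSE)
  }
  imageTowerFwd(patches, weights, config)$pooled
}

#' Embed one frame as a sequence
#'
#' Like \code{\link{embedImage}} but returns the full patch-token
#' sequence after the tower blocks (the default input to the
#' modality encoder).
#'
#' @inheritParams embedImage
#' @return (H/P)(W/P) x dOut matrix.
#' @export
embedImageSequence <- function(frame, config, weights) {
  patches <- patchify(frame, config$patchSize)
  imageTowerFwd(patches, weights, config)$seq
}

.PAD <- "<pad>"
.UNK <- "<unk>"

.tokenize <- function(text) {
  toks <- strsplit(tolower(trimws(text)), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Build a whitespace-token vocabulary
#'
#' Lowercased whitespace tokens with corpus frequency at least
#' \code{minCount}, ordered by (frequency descending, token
#' lexicographic); ids 1 and 2 are reserved for the padding and unknown
#' tokens.
#'
#' @param corpus non-empty character vector.
#' @param minCount minimum corpus frequency (default 1).
#' @return named integer vector token -> id, including \code{"<pad>"}
#'   and \code{"<unk>"}.
#' @export
buildVocab <- function(corpus, minCount = 1L) {
  if (length(corpus) == 0L) stop("corpus must be non-empty", call. = FALSE)
  toks <- unlist(lapply(corpus, .tokenize))
  counts <- table(toks)
  keep <- counts[counts >= minCount]
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  tokens <- names(keep)[ord]
  ids <- seq_along(tokens) + 2L
  stats::setNames(c(1L, 2L, ids), c(.PAD, .UNK, tokens))
}

#' Map a text to token ids
#'
#' @param text character scalar.
#' @param vocab output of \code{\link{buildVocab}}.
#' @return integer vector of ids; empty text maps to the single padding
#'   id.
#' @export
tokenIds <- function(text, vocab) {
  toks <- .tokenize(text)
  if (length(toks) == 0L) return(vocab[[.PAD]])
  ids <- vocab[toks]
  ids[is.na(ids)] <- vocab[[.UNK]]
  unname(ids)
}

#' Initialise the text tower
#'
#' @param config a \code{\link{towerConfig}}.
#' @param vocab output of \code{\link{buildVocab}}.
#' @return weight list with the token embedding matrix \code{emb}
#'   (vocab x dOut).
#' @export
initTextTower <- function(config, vocab) {
  withSeed(config$seed + 1L, {
    list(emb = initMat(length(vocab), config$dOut))
  })
}

#' Embed a text
#'
#' Token-id lookup into the learned embedding matrix plus sinusoidal
#' positional encoding (if configured). Empty texts map to the single
#' padding token, so L >= 1 always.
#'
#' @param text character scalar.
#' @param vocab output of \code{\link{buildVocab}}.
#' @param config a \code{\link{towerConfig}}.
#' @param weights output of \code{\link{initTextTower}} (or trained).
#' @return L x dOut matrix, L = token count.
#' @export
embedText <- function(text, vocab, config, weights) {
  ids <- tokenIds(text, vocab)
  X <- weights$emb[ids, , drop = FALSE]
  if (isTRUE(config$usePositional)) {
    X <- X + positionalEncoding(nrow(X), ncol(X))
  }
  X
}

#' Write a table of precomputed embeddings
#'
#' TSV with columns \code{source_id}, \code{position}, then D float
#' columns \code{V1..VD}; the import path for embeddings computed by an
#' external pretrained model.
#'
#' @param table named list of L x D matrices (names are source ids).
#' @param path output file.
#' @export
writePrecomputedEmbeddings <- function(table, path) {
  rows <- lapply(names(table), function(id) {
    M <- table[[id]]
    data.frame(source_id = id, position = seq_len(nrow(M)) - 1L,
               M, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(source_id = character(), position = integer())
  } else {
    names(df) <- c("source_id", "position",
                   paste0("V", seq_len(ncol(df) - 2L)))
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load precomputed embeddings
#'
#' @param path TSV written in the \code{\link{writePrecomputedEmbeddings}}
#'   layout.
#' @return named list of L x D matrices keyed by source id (empty list
#'   for an empty file).
#' @export
loadPrecomputedEmbeddings <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("embedding file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(list())
  vcols <- setdiff(names(df), c("source_id", "position"))
  vals <- as.matrix(df[vcols])
  if (anyNA(vals) || !is.numeric(vals)) {
    stop("inconsistent embedding dimensions in file", call. = FALSE)
  }
  ids <- unique(df$source_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$source_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    unname(as.matrix(sub[vcols]))
  })
  stats::setNames(out, ids)
}
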