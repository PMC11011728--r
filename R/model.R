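# PhaseModel assembly: initialisation, the per-sample forward/backward
# passes through the full stack, and bit-exact checkpoint I/O (flat
# binary of doubles + JSON metadata).

#' Structural model configuration
#'
#' Collects the tower, encoder, head and classifier dimensions. The
#' desk preset (defaults) keeps all widths at 32 so the whole pipeline
#' trains on one CPU; the published setting corresponds to
#' \code{dOut = dModel = 768}, \code{nLayers = 12}.
#'
#' @param tower a \code{\link{towerConfig}}.
#' @param encoder an \code{\link{encoderConfig}}.
#' @param dJoint per-modality projection width (default tower dOut).
#' @param mlpHidden MLP hidden width (default 128).
#' @param frameSize frame side in pixels (default 64).
#' @param nClasses number of phases (default 7).
#' @return list of class \code{"ModelConfig"}.
#' @export
modelConfigList <- function(tower = towerConfig(), encoder = encoderConfig(),
                            dJoint = tower$dOut, mlpHidden = 128L,
                            frameSize = 64L, nClasses = 7L) {
  stopifnot(tower$dOut == encoder$dModel)
  structure(list(tower = tower, encoder = encoder,
                 dJoint = as.integer(dJoint),
                 mlpHidden = as.integer(mlpHidden),
                 frameSize = as.integer(frameSize),
                 nClasses = as.integer(nClasses)),
            class = "ModelConfig")
}

#' Initialise a PhaseModel
#'
#' Builds all weight arrays with seeded uniform 1/sqrt(fan_in)
#' initialisation. In \code{"two_tower"} mode the bundle holds the two
#' towers, two encoders, two projection heads and the MLP; in
#' \code{"one_tower"} mode a single shared encoder replaces the pair
#' and the MLP consumes its pooled output directly.
#'
#' @param vocab output of \code{\link{buildVocab}}.
#' @param config a \code{\link{modelConfigList}}.
#' @param mode \code{"two_tower"} (default) or \code{"one_tower"}.
#' @param seed master seed; per-component seeds are derived from it.
#' @return a \linkS4class{PhaseModel}.
#' @export
initPhaseModel <- function(vocab, config = modelConfigList(),
                           mode = c("two_tower", "one_tower"), seed = 1L) {
  mode <- match.arg(mode)
  tc <- config$tower; ec <- config$encoder
  tc$seed <- childSeed(seed, "towers")
  d <- tc$dOut
  w <- list(imgTower = initImageTower(tc, config$frameSize),
            txtTower = initTextTower(tc, vocab))
  if (mode == "two_tower") {
    eci <- ec; eci$seed <- childSeed(seed, "towers") + 7L
    ect <- ec; ect$seed <- childSeed(seed, "towers") + 13L
    w$imgEnc <- initEncoderWeights(eci)
    w$txtEnc <- initEncoderWeights(ect)
    w$imgHead <- initProjectionHead(d, dOut = config$dJoint,
                                    seed = childSeed(seed, "towers") + 19L)
    w$txtHead <- initProjectionHead(d, dOut = config$dJoint,
                                    seed = childSeed(seed, "towers") + 23L)
    w$mlp <- initMlp(2L * config$dJoint, config$mlpHidden, config$nClasses,
                     seed = childSeed(seed, "classifier"))
  } else {
    ecs <- ec; ecs$seed <- childSeed(seed, "onetower")
    w$enc <- initEncoderWeights(ecs)
    w$mlp <- initMlp(d, config$mlpHidden, config$nClasses,
                     seed = childSeed(seed, "classifier"))
  }
  new("PhaseModel", weights = w, config = unclass(config),
      vocab = vocab, mode = mode)
}

# Text input sequence: embedding lookup + positional encoding.
.txtInput <- function(ids, emb, usePositional) {
  X <- emb[ids, , drop = FALSE]
  if (isTRUE(usePositional)) X <- X + positionalEncoding(nrow(X), ncol(X))
  X
}

# Two-tower forward for one (patches, token-ids) pair, with caches.
twoTowerFwd <- function(patches, ids, w, cfg, training = FALSE) {
  tf <- imageTowerFwd(patches, w$imgTower, cfg$tower)
  ie <- encFwd(tf$seq, w$imgEnc, cfg$encoder, training = training)
  ih <- headFwd(ie$pooled, w$imgHead)
  X0 <- .txtInput(ids, w$txtTower$emb, cfg$tower$usePositional)
  te <- encFwd(X0, w$txtEnc, cfg$encoder, training = training)
  th <- headFwd(te$pooled, w$txtHead)
  list(x = ih$out, y = th$out, tf = tf, ie = ie, ih = ih,
       te = te, th = th, ids = ids)
}

# Backward for one pair given d(loss)/dx and d(loss)/dy.
twoTowerBwd <- function(fwd, w, cfg, dx, dy) {
  gih <- headBwd(fwd$ih, dx)
  gie <- encBwd(fwd$ie, w$imgEnc, dPooled = gih$dIn)
  git <- imageTowerBwd(fwd$tf, w$imgTower, gie$dX)
  gth <- headBwd(fwd$th, dy)
  gte <- encBwd(fwd$te, w$txtEnc, dPooled = gth$dIn)
  dEmb <- matrix(0, nrow(w$txtTower$emb), ncol(w$txtTower$emb))
  for (l in seq_along(fwd$ids)) {
    dEmb[fwd$ids[l], ] <- dEmb[fwd$ids[l], ] + gte$dX[l, ]
  }
  list(imgTower = git$dW,
       txtTower = list(emb = dEmb),
       imgEnc = gie$dBlocks,
       txtEnc = gte$dBlocks,
       imgHead = gih$dW,
       txtHead = gth$dW)
}

# One-tower forward: towers -> sequence concat (image first) ->
# shared encoder -> pooled -> MLP.
oneTowerFwd <- function(patches, ids, w, cfg, training = FALSE) {
  tf <- imageTowerFwd(patches, w$imgTower, cfg$tower)
  X0 <- .txtInput(ids, w$txtTower$emb, cfg$tower$usePositional)
  Limg <- nrow(tf$seq)
  ef <- encFwd(rbind(tf$seq, X0), w$enc, cfg$encoder, training = training)
  mf <- mlpFwd(ef$pooled, w$mlp)
  list(probs = mf$probs, logits = mf$logits, tf = tf, ef = ef, mf = mf,
       ids = ids, Limg = Limg)
}

oneTowerBwd <- function(fwd, w, cfg, dLogits) {
  gm <- mlpBwd(fwd$mf, dLogits)
  ge <- encBwd(fwd$ef, w$enc, dPooled = gm$dIn)
  dImg <- ge$dX[seq_len(fwd$Limg), , drop = FALSE]
  dTxt <- ge$dX[-seq_len(fwd$Limg), , drop = FALSE]
  git <- imageTowerBwd(fwd$tf, w$imgTower, dImg)
  dEmb <- matrix(0, nrow(w$txtTower$emb), ncol(w$txtTower$emb))
  for (l in seq_along(fwd$ids)) {
    dEmb[fwd$ids[l], ] <- dEmb[fwd$ids[l], ] + dTxt[l, ]
  }
  list(imgTower = git$dW, txtTower = list(emb = dEmb),
       enc = ge$dBlocks, mlp = gm$dW)
}

#' Joint representation of one frame/text pair
#'
#' Runs the frozen two-tower stack: image tower, image encoder,
#' projection head; text tower, text encoder, projection head; then
#' concatenates the two projected vectors (image first).
#'
#' @param model a two-tower \linkS4class{PhaseModel}.
#' @param frame H x W x 3 array.
#' @param text character scalar.
#' @return numeric vector of length \code{2 * dJoint}.
#' @export
jointRepresentation <- function(model, frame, text) {
  stopifnot(model@mode == "two_tower")
  cfg <- model@config; w <- model@weights
  patches <- patchify(frame, cfg$tower$patchSize)
  ids <- tokenIds(text, model@vocab)
  f <- twoTowerFwd(patches, ids, w, cfg)
  combineJoint(f$x, f$y)
}

#' Predict the phase of one frame/text pair
#'
#' @param model a \linkS4class{PhaseModel}.
#' @param frame H x W x 3 array.
#' @param text character scalar.
#' @return list with \code{probabilities} and \code{predictedPhase}
#'   (see \code{\link{mlpForward}}).
#' @export
predictPhase <- function(model, frame, text) {
  cfg <- model@config; w <- model@weights
  patches <- patchify(frame, cfg$tower$patchSize)
  ids <- tokenIds(text, model@vocab)
  if (model@mode == "two_tower") {
    f <- twoTowerFwd(patches, ids, w, cfg)
    j <- applyScaler(combineJoint(f$x, f$y), w$scaler)
    mlpForward(j, w$mlp)
  } else {
    f <- oneTowerFwd(patches, ids, w, cfg)
    list(probabilities = f$probs, predictedPhase = which.max(f$probs) - 1L)
  }
}

#' Save a PhaseModel checkpoint
#'
#' Writes all weight arrays as a flat little-endian binary of doubles
#' (\code{<prefix>.bin}) plus a JSON metadata file
#' (\code{<prefix>.json}) recording array names, dimensions, the
#' structural config, vocabulary and mode. The round trip is bit-exact.
#'
#' @param model a \linkS4class{PhaseModel}.
#' @param prefix path prefix for the two files.
#' @return the prefix, invisibly.
#' @export
saveModel <- function(model, prefix) {
  flat <- flattenWeights(model@weights)
  cfg <- model@config
  cfg$tower <- unclass(cfg$tower)
  cfg$encoder <- unclass(cfg$encoder)
  meta <- list(
    arrays = lapply(flat, function(x) {
      if (is.matrix(x)) dim(x) else length(x)
    }),
    config = unclass(cfg),
    vocab = as.list(model@vocab),
    mode = model@mode)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (x in flat) writeBin(as.numeric(x), con, size = 8L, endian = "little")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Load a PhaseModel checkpoint
#'
#' @param prefix path prefix used in \code{\link{saveModel}}.
#' @return a \linkS4class{PhaseModel}.
#' @export
loadModel <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  flat <- list()
  for (nm in names(meta$arrays)) {
    dims <- meta$arrays[[nm]]
    n <- prod(dims)
    x <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
    if (length(dims) == 2L) x <- matrix(x, dims[1], dims[2])
    flat[[nm]] <- x
  }
  cfg <- meta$config
  cfg$tower <- structure(as.list(cfg$tower), class = "TowerConfig")
  cfg$encoder <- structure(as.list(cfg$encoder), class = "EncoderConfig")
  new("PhaseModel", weights = unflattenWeights(flat), config = cfg,
      vocab = stats::setNames(as.integer(unlist(meta$vocab)),
                              names(meta$vocab)),
      mode = meta$mode)
}
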