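# End-to-end orchestration: the default synthetic benchmark,
# cross-validated evaluation, the one-encoder ablation, and frame-level
# inference.

#' Generate the default synthetic benchmark
#'
#' Ten synthetic videos sampled at 0.03 frames/s (about 700 frame/text
#' pairs given the published phase durations), 64-pixel frames, noise
#' sd 0.05, text variability 0.3, instrument overlay probability 0.3
#' and smoke probability 0.2.
#'
#' @param seed master seed.
#' @param outDir output directory.
#' @param nVideos number of videos (default 10).
#' @param fps sampling rate (default 0.03).
#' @return a \linkS4class{DatasetManifest}.
#' @export
benchmarkDataset <- function(seed = 1L, outDir = tempfile("phasebench_"),
                             nVideos = 10L, fps = 0.03) {
  generateDataset(nVideos = nVideos, fps = fps, seed = seed, outDir = outDir)
}

# Train towers then classifier on the given rows; returns trained model.
.trainTwoTower <- function(manifest, vocab, cfg, tc, rows,
                           tcCl = classifierTrainConfig(tc$seed)) {
  model <- initPhaseModel(vocab, cfg, mode = "two_tower", seed = tc$seed)
  inputs <- prepareInputs(manifest, model, rows)
  tw <- trainTowers(manifest, model, tc, inputs = inputs)
  cl <- trainClassifier(manifest, tw$model, tcCl, inputs = inputs)
  list(model = cl$model, towerLoss = tw$lossTrace,
       classifierLoss = cl$lossTrace)
}

#' Train the full two-tower pipeline on a manifest's training split
#'
#' Contrastive tower training followed by frozen-feature classifier
#' training on the manifest's training-partition videos, then
#' evaluation on the held-out test-partition frames with their paired
#' texts.
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param tc tower \code{\link{trainConfig}}.
#' @param tcCl classifier \code{\link{trainConfig}}.
#' @param cfg a \code{\link{modelConfigList}}.
#' @return list with \code{model}, \code{report} (test-set
#'   \linkS4class{EvalReport}), \code{towerLoss}, \code{classifierLoss}.
#' @export
trainPipeline <- function(manifest, tc = deskTrainConfig(epochs = 8L),
                          tcCl = classifierTrainConfig(tc$seed),
                          cfg = modelConfigList()) {
  rec <- manifest@records
  trainVids <- manifest@split$video_id[manifest@split$partition == "train"]
  trainRows <- which(rec$video_id %in% trainVids)
  testRows <- which(!rec$video_id %in% trainVids)
  vocab <- buildVocab(rec$text)
  fit <- .trainTwoTower(manifest, vocab, cfg, tc, trainRows, tcCl)
  report <- if (length(testRows)) {
    suppressWarnings(.evalRows(manifest, fit$model, testRows))
  } else NULL
  list(model = fit$model, report = report, towerLoss = fit$towerLoss,
       classifierLoss = fit$classifierLoss)
}

# Evaluate a model on the given rows using the paired texts.
.evalRows <- function(manifest, model, rows, foldId = NA_integer_) {
  inputs <- prepareInputs(manifest, model, rows)
  pred <- vapply(seq_along(inputs$patches), function(i) {
    if (model@mode == "two_tower") {
      f <- twoTowerFwd(inputs$patches[[i]], inputs$ids[[i]],
                       model@weights, model@config)
      j <- applyScaler(combineJoint(f$x, f$y), model@weights$scaler)
      p <- mlpForward(j, model@weights$mlp)
    } else {
      f <- oneTowerFwd(inputs$patches[[i]], inputs$ids[[i]],
                       model@weights, model@config)
      p <- list(predictedPhase = which.max(f$probs) - 1L)
    }
    p$predictedPhase
  }, integer(1))
  cm <- confusionMatrix(inputs$phase, pred, model@config$nClasses)
  classificationMetrics(cm, foldId = foldId)
}

#' Cross-validated evaluation of the two-tower pipeline
#'
#' Splits videos into k folds; for each fold, trains the towers (with
#' the contrastive loss) and then the classifier on the other folds'
#' videos, and evaluates on the held-out fold's frames with their
#' paired texts. No video appears in both partitions of any fold.
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param k fold count (default 5).
#' @param tc tower \code{\link{trainConfig}}.
#' @param tcCl classifier \code{\link{trainConfig}}.
#' @param cfg a \code{\link{modelConfigList}}.
#' @param verbose print per-fold progress.
#' @return list with \code{reports} (per-fold
#'   \linkS4class{EvalReport}s), \code{aggregate} (mean/sd table),
#'   and \code{plan} (the \linkS4class{FoldPlan}).
#' @export
runCrossval <- function(manifest, k = 5L, tc = deskTrainConfig(epochs = 8L),
                        tcCl = classifierTrainConfig(tc$seed),
                        cfg = modelConfigList(), verbose = FALSE) {
  rec <- manifest@records
  vids <- unique(rec$video_id)
  plan <- kfoldSplit(vids, k = k, seed = childSeed(tc$seed, "folds"))
  vocab <- buildVocab(rec$text)
  reports <- vector("list", k)
  for (fold in seq_len(k)) {
    testVids <- names(plan@assignment)[plan@assignment == fold]
    trainRows <- which(!rec$video_id %in% testVids)
    testRows <- which(rec$video_id %in% testVids)
    stopifnot(length(intersect(rec$video_id[trainRows],
                               rec$video_id[testRows])) == 0L)
    fit <- .trainTwoTower(manifest, vocab, cfg, tc, trainRows, tcCl)
    reports[[fold]] <- suppressWarnings(
      .evalRows(manifest, fit$model, testRows, fold))
    if (verbose) {
      message(sprintf("fold %d: accuracy %.4f", fold,
                      reports[[fold]]@accuracy))
    }
  }
  list(reports = reports, aggregate = aggregateFolds(reports), plan = plan)
}

#' One-encoder vs two-encoder ablation
#'
#' Runs both arms over an identical fold plan and seed: the two-tower
#' arm is the default contrastive pipeline; the one-tower arm
#' concatenates the embedding sequences into a single shared encoder
#' trained end-to-end with cross-entropy. Returns per-fold paired
#' accuracies and the paired t-test on them.
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param tc tower \code{\link{trainConfig}} for the two-tower arm.
#' @param k fold count (default 5).
#' @param tcCl classifier \code{\link{trainConfig}}.
#' @param tcOne \code{\link{trainConfig}} for the one-tower arm.
#' @param cfg a \code{\link{modelConfigList}}.
#' @param verbose print per-fold progress.
#' @return list with \code{table} (per-fold accuracies of both arms),
#'   \code{test} (the \code{\link{pairedTTest}} result), and
#'   \code{plan}.
#' @export
runAblation <- function(manifest, tc = deskTrainConfig(epochs = 8L), k = 5L,
                        tcCl = classifierTrainConfig(tc$seed),
                        tcOne = oneTowerTrainConfig(tc$seed, epochs = tc$epochs),
                        cfg = modelConfigList(), verbose = FALSE) {
  rec <- manifest@records
  vids <- unique(rec$video_id)
  plan <- kfoldSplit(vids, k = k, seed = childSeed(tc$seed, "folds"))
  vocab <- buildVocab(rec$text)
  accTwo <- numeric(k); accOne <- numeric(k)
  for (fold in seq_len(k)) {
    testVids <- names(plan@assignment)[plan@assignment == fold]
    trainRows <- which(!rec$video_id %in% testVids)
    testRows <- which(rec$video_id %in% testVids)
    fitTwo <- .trainTwoTower(manifest, vocab, cfg, tc, trainRows, tcCl)
    accTwo[fold] <- suppressWarnings(
      .evalRows(manifest, fitTwo$model, testRows, fold))@accuracy
    oneModel <- initPhaseModel(vocab, cfg, mode = "one_tower", seed = tc$seed)
    fitOne <- trainOneTower(manifest, oneModel, tcOne, rows = trainRows)
    accOne[fold] <- suppressWarnings(
      .evalRows(manifest, fitOne$model, testRows, fold))@accuracy
    if (verbose) {
      message(sprintf("fold %d: two-tower %.4f, one-tower %.4f",
                      fold, accTwo[fold], accOne[fold]))
    }
  }
  list(table = data.frame(fold = seq_len(k), two_tower = accTwo,
                          one_tower = accOne),
       test = suppressWarnings(pairedTTest(accTwo, accOne)),
       plan = plan)
}

#' Frame-level inference
#'
#' Classifies each frame through the full trained stack. Because the
#' classifier consumes a joint image/text representation while a plain
#' video frame carries no text, two inference modes are provided:
#' \describe{
#'   \item{canonical-scan (default)}{pair the frame with each of the 7
#'     canonical phase texts; hypothesis k is scored by the predicted
#'     probability of phase k given text k, and the best-scoring
#'     hypothesis wins. Reported probabilities are the normalised
#'     hypothesis scores.}
#'   \item{fixed-text}{pair every frame with a constant neutral text
#'     and read the classifier output directly.}
#' }
#'
#' @param input a frame array, a path to one image, a directory of
#'   images, or a list of frame arrays.
#' @param model a trained two-tower \linkS4class{PhaseModel}.
#' @param catalog the \linkS4class{PhaseCatalog} (canonical texts).
#' @param mode \code{"canonical-scan"} or \code{"fixed-text"}.
#' @return data.frame with columns \code{source}, \code{predicted_phase}
#'   and \code{p0..p6}.
#' @export
inferPhases <- function(input, model, catalog = buildPhaseCatalog(),
                        mode = c("canonical-scan", "fixed-text")) {
  mode <- match.arg(mode)
  frames <- list(); sources <- character()
  if (is.character(input)) {
    paths <- input
    if (length(input) == 1L && dir.exists(input)) {
      paths <- list.files(input, pattern = "\\.png$", full.names = TRUE,
                          recursive = TRUE)
      if (length(paths) == 0L) {
        stop(sprintf("no PNG frames found in '%s'", input), call. = FALSE)
      }
    }
    for (p in paths) {
      fr <- tryCatch(png::readPNG(p), error = function(e) NULL)
      if (is.null(fr)) {
        warning(sprintf("unreadable image skipped: %s", p))
        next
      }
      if (length(dim(fr)) == 2L) fr <- array(rep(fr, 3L), dim = c(dim(fr), 3L))
      frames[[length(frames) + 1L]] <- fr
      sources <- c(sources, p)
    }
  } else if (is.array(input) && length(dim(input)) == 3L) {
    frames <- list(input); sources <- "frame"
  } else if (is.list(input)) {
    frames <- input
    sources <- if (!is.null(names(input))) names(input)
               else sprintf("frame%03d", seq_along(input))
  } else {
    stop("unsupported input type", call. = FALSE)
  }
  if (length(frames) == 0L) stop("no readable frames", call. = FALSE)
  texts <- canonicalTexts(catalog)
  nC <- model@config$nClasses
  out <- lapply(seq_along(frames), function(i) {
    if (mode == "canonical-scan") {
      scores <- vapply(seq_len(nC), function(kk) {
        predictPhase(model, frames[[i]], texts[kk])$probabilities[kk]
      }, numeric(1))
      probs <- scores / sum(scores)
    } else {
      probs <- predictPhase(model, frames[[i]],
                            "laparoscopic surgical video frame")$probabilities
    }
    c(list(source = sources[i], predicted_phase = which.max(probs) - 1L),
      stats::setNames(as.list(probs), paste0("p", seq_len(nC) - 1L)))
  })
  do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
}

#' Write per-frame predictions as CSV
#'
#' @param predictions output of \code{\link{inferPhases}}.
#' @param path output CSV path.
#' @export
writePredictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
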