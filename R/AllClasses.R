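#' @import methods
NULL

#' PhaseCatalog: the seven ordered phases of laparoscopic cholecystectomy
#'
#' Holds, for each of the seven surgical phases, its identifier (0-6, in
#' procedural order), display name, the mean and standard deviation of its
#' duration in seconds, a canonical one-sentence text description, and the
#' rendering parameters of its synthetic image motif.
#'
#' @slot phases data.frame with columns \code{phase_id}, \code{name},
#'   \code{duration_mean}, \code{duration_sd}, \code{canonical_text},
#'   \code{keyword}; exactly seven rows in procedural order.
#' @slot motifParams list of length 7; per-phase rendering parameters.
#' @slot motifScheme character scalar naming the registered rendering scheme.
#' @export
setClass("PhaseCatalog",
  representation(phases = "data.frame",
                 motifParams = "list",
                 motifScheme = "character"))

setValidity("PhaseCatalog", function(object) {
  ph <- object@phases
  msgs <- character()
  need <- c("phase_id", "name", "duration_mean", "duration_sd",
            "canonical_text", "keyword")
  if (!all(need %in% names(ph))) {
    return(paste("phases must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(ph) != 7L) msgs <- c(msgs, "exactly 7 phases required")
  if (!identical(ph$phase_id, 0:6)) {
    msgs <- c(msgs, "phase_id must be 0..6 in order")
  }
  if (any(ph$duration_mean <= 0) || any(ph$duration_sd <= 0)) {
    msgs <- c(msgs, "duration_mean and duration_sd must be positive")
  }
  if (anyDuplicated(ph$canonical_text) || any(!nzchar(ph$canonical_text))) {
    msgs <- c(msgs, "canonical_text must be non-empty and unique per phase")
  }
  if (length(object@motifParams) != nrow(ph)) {
    msgs <- c(msgs, "motifParams must have one entry per phase")
  }
  if (length(msgs)) msgs else TRUE
})

#' DatasetManifest: records, split and provenance of a synthetic dataset
#'
#' @slot records data.frame with columns \code{video_id},
#'   \code{frame_index}, \code{path}, \code{phase_id}, \code{text}.
#' @slot split data.frame with columns \code{video_id}, \code{partition}
#'   (\code{"train"} or \code{"test"}).
#' @slot seed integer seed the dataset was generated from.
#' @slot generatorParams list; full parameter record for regeneration.
#' @slot dir character; directory that stored frame paths resolve against.
#' @export
setClass("DatasetManifest",
  representation(records = "data.frame",
                 split = "data.frame",
                 seed = "integer",
                 generatorParams = "list",
                 dir = "character"))

setValidity("DatasetManifest", function(object) {
  rec <- object@records
  msgs <- character()
  need <- c("video_id", "frame_index", "path", "phase_id", "text")
  if (!all(need %in% names(rec))) {
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(rec[c("video_id", "frame_index")])) {
    msgs <- c(msgs, "(video_id, frame_index) must be unique")
  }
  if (any(rec$phase_id < 0L | rec$phase_id > 6L)) {
    msgs <- c(msgs, "phase_id must lie in 0..6")
  }
  sp <- object@split
  if (!all(c("video_id", "partition") %in% names(sp))) {
    msgs <- c(msgs, "split must have columns video_id, partition")
  } else {
    if (!setequal(sp$video_id, unique(rec$video_id))) {
      msgs <- c(msgs, "split must label exactly the videos in records")
    }
    if (!all(sp$partition %in% c("train", "test"))) {
      msgs <- c(msgs, "partition labels must be 'train' or 'test'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' FoldPlan: a k-fold assignment of whole videos
#'
#' @slot k integer fold count.
#' @slot assignment named integer vector mapping video_id to fold id (1..k).
#' @slot seed integer seed used for the shuffle.
#' @export
setClass("FoldPlan",
  representation(k = "integer", assignment = "integer", seed = "integer"))

setValidity("FoldPlan", function(object) {
  msgs <- character()
  if (object@k < 2L) msgs <- c(msgs, "k must be at least 2")
  a <- object@assignment
  if (is.null(names(a)) || anyDuplicated(names(a))) {
    msgs <- c(msgs, "assignment must be named by unique video ids")
  }
  if (length(a) && (min(a) < 1L || max(a) > object@k)) {
    msgs <- c(msgs, "fold ids must lie in 1..k")
  }
  if (length(a) >= object@k) {
    sizes <- tabulate(a, nbins = object@k)
    if (diff(range(sizes)) > 1L) {
      msgs <- c(msgs, "fold sizes must differ by at most 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' EvalReport: confusion matrix and summary metrics for one evaluation
#'
#' @slot confusion integer matrix (rows = true phase, cols = predicted).
#' @slot accuracy numeric scalar.
#' @slot weightedPrecision numeric scalar (support-weighted mean).
#' @slot weightedRecall numeric scalar (support-weighted mean).
#' @slot perPhase data.frame with columns \code{phase_id}, \code{precision},
#'   \code{recall}, \code{support}.
#' @slot foldId integer; which fold this report belongs to (NA if none).
#' @export
setClass("EvalReport",
  representation(confusion = "matrix",
                 accuracy = "numeric",
                 weightedPrecision = "numeric",
                 weightedRecall = "numeric",
                 perPhase = "data.frame",
                 foldId = "integer"))

setValidity("EvalReport", function(object) {
  msgs <- character()
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) msgs <- c(msgs, "confusion must be square")
  if (any(cm < 0) || any(cm != round(cm))) {
    msgs <- c(msgs, "confusion entries must be non-negative counts")
  }
  tot <- sum(cm)
  if (tot > 0 && abs(object@accuracy - sum(diag(cm)) / tot) > 1e-8) {
    msgs <- c(msgs, "accuracy must equal trace/total")
  }
  if (length(msgs)) msgs else TRUE
})

#' PhaseModel: the trainable weight bundle of the recognition pipeline
#'
#' Bundles the image and text towers, the per-modality Transformer
#' encoders, the projection heads, the MLP classifier head, the text
#' vocabulary, and the structural configuration they were built from.
#'
#' @slot weights named list of numeric matrices/vectors.
#' @slot config list; structural configuration (dimensions, layer counts).
#' @slot vocab named integer vector mapping token to id.
#' @slot mode character; \code{"two_tower"} or \code{"one_tower"}.
#' @export
setClass("PhaseModel",
  representation(weights = "list",
                 config = "list",
                 vocab = "integer",
                 mode = "character"))

setValidity("PhaseModel", function(object) {
  msgs <- character()
  if (!object@mode %in% c("two_tower", "one_tower")) {
    msgs <- c(msgs, "mode must be 'two_tower' or 'one_tower'")
  }
  ok <- unlist(rapply(object@weights, function(w) all(is.finite(w)),
                      how = "unlist"))
  if (!all(ok)) msgs <- c(msgs, "all weights must be finite")
  if (length(msgs)) msgs else TRUE
})
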