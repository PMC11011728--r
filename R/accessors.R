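# Accessor generics and show methods for the core S4 classes.

#' @rdname PhaseCatalog-class
#' @param object a \linkS4class{PhaseCatalog}
#' @export
setGeneric("phaseTable", function(object) standardGeneric("phaseTable"))

#' @rdname PhaseCatalog-class
#' @export
setMethod("phaseTable", "PhaseCatalog", function(object) object@phases)

#' @rdname PhaseCatalog-class
#' @export
setGeneric("canonicalTexts", function(object) standardGeneric("canonicalTexts"))

#' @rdname PhaseCatalog-class
#' @export
setMethod("canonicalTexts", "PhaseCatalog", function(object) {
  stats::setNames(object@phases$canonical_text, object@phases$name)
})

#' @rdname DatasetManifest-class
#' @param object a \linkS4class{DatasetManifest}
#' @export
setGeneric("manifestRecords", function(object) standardGeneric("manifestRecords"))

#' @rdname DatasetManifest-class
#' @export
setMethod("manifestRecords", "DatasetManifest", function(object) object@records)

#' @rdname DatasetManifest-class
#' @export
setGeneric("manifestSplit", function(object) standardGeneric("manifestSplit"))

#' @rdname DatasetManifest-class
#' @export
setMethod("manifestSplit", "DatasetManifest", function(object) object@split)

#' @rdname FoldPlan-class
#' @param object a \linkS4class{FoldPlan}
#' @export
setGeneric("foldAssignment", function(object) standardGeneric("foldAssignment"))

#' @rdname FoldPlan-class
#' @export
setMethod("foldAssignment", "FoldPlan", function(object) object@assignment)

#' @rdname EvalReport-class
#' @param object an \linkS4class{EvalReport}
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(object) object@confusion)

#' @rdname EvalReport-class
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))

#' @rdname EvalReport-class
#' @export
setMethod("metrics", "EvalReport", function(object) {
  c(accuracy = object@accuracy,
    weighted_precision = object@weightedPrecision,
    weighted_recall = object@weightedRecall)
})

#' @rdname PhaseModel-class
#' @param object a \linkS4class{PhaseModel}
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))

#' @rdname PhaseModel-class
#' @export
setMethod("modelWeights", "PhaseModel", function(object) object@weights)

#' @rdname PhaseModel-class
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname PhaseModel-class
#' @export
setMethod("modelConfig", "PhaseModel", function(object) object@config)

setMethod("show", "PhaseCatalog", function(object) {
  cat("PhaseCatalog with", nrow(object@phases), "phases (scheme:",
      object@motifScheme, ")\n")
  print(object@phases[, c("phase_id", "name", "duration_mean", "duration_sd")])
})

setMethod("show", "DatasetManifest", function(object) {
  rec <- object@records
  cat(sprintf("DatasetManifest: %d frames, %d videos (seed %d)\n",
              nrow(rec), length(unique(rec$video_id)), object@seed))
  tab <- table(object@split$partition)
  cat("  split:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: k=%d over %d videos (seed %d)\n",
              object@k, length(object@assignment), object@seed))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport (fold %s): accuracy %.4f, weighted precision %.4f, weighted recall %.4f over %d frames\n",
    ifelse(is.na(object@foldId), "-", object@foldId),
    object@accuracy, object@weightedPrecision, object@weightedRecall,
    sum(object@confusion)))
})

setMethod("show", "PhaseModel", function(object) {
  np <- sum(vapply(object@weights, length, integer(1)))
  cat(sprintf("PhaseModel (%s): %d parameter arrays, %d parameters, vocab %d\n",
              object@mode, length(object@weights), np, length(object@vocab)))
})
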