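# Evaluation machinery: confusion matrix, weighted metrics, k-fold
# planning, fold aggregation, and the paired t-test used to compare the
# one- and two-encoder models.

#' Confusion matrix
#'
#' @param yTrue,yPred integer label vectors of equal length, values in
#'   \code{0..nClasses-1}.
#' @param nClasses number of classes (default 7).
#' @return nClasses x nClasses integer matrix; entry (t, p) counts
#'   frames with true class t predicted p.
#' @export
confusionMatrix <- function(yTrue, yPred, nClasses = 7L) {
  stopifnot(length(yTrue) == length(yPred))
  if (any(yTrue < 0L | yTrue >= nClasses) ||
      any(yPred < 0L | yPred >= nClasses)) {
    stop("labels out of range", call. = FALSE)
  }
  cm <- matrix(0L, nClasses, nClasses,
               dimnames = list(true = 0:(nClasses - 1L),
                               pred = 0:(nClasses - 1L)))
  for (i in seq_along(yTrue)) {
    cm[yTrue[i] + 1L, yPred[i] + 1L] <- cm[yTrue[i] + 1L, yPred[i] + 1L] + 1L
  }
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision TP/(TP+FP) and recall TP/(TP+FN); weighted
#' averages use true-class supports as weights. A class with zero
#' predicted positives gets precision 0 (with a warning); a class with
#' zero support contributes nothing to the weighted averages. The
#' weighted recall coincides with the accuracy (micro identity).
#'
#' @param confusion square count matrix (rows = true, cols = predicted).
#' @param foldId optional fold identifier recorded in the report.
#' @return an \linkS4class{EvalReport}.
#' @export
classificationMetrics <- function(confusion, foldId = NA_integer_) {
  cm <- as.matrix(confusion)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  predPos <- colSums(cm)
  precision <- ifelse(predPos > 0, tp / predPos, 0)
  if (any(predPos == 0 & support > 0)) {
    warning("class with zero predicted positives; precision set to 0")
  }
  recall <- ifelse(support > 0, tp / support, 0)
  acc <- sum(tp) / total
  wPrec <- sum(precision * support) / total
  wRec <- sum(recall * support) / total
  new("EvalReport",
      confusion = matrix(as.integer(cm), k, k, dimnames = dimnames(cm)),
      accuracy = acc, weightedPrecision = wPrec, weightedRecall = wRec,
      perPhase = data.frame(phase_id = 0:(k - 1L), precision = precision,
                            recall = recall, support = as.integer(support),
                            row.names = NULL),
      foldId = as.integer(foldId))
}

#' Plan a k-fold split over whole videos
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes
#' differ by at most one and no video straddles folds.
#'
#' @param videoIds character vector of video ids.
#' @param k fold count (default 5).
#' @param seed integer seed.
#' @return a \linkS4class{FoldPlan}.
#' @export
kfoldSplit <- function(videoIds, k = 5L, seed = 1L) {
  videoIds <- unique(as.character(videoIds))
  if (k > length(videoIds)) {
    stop(sprintf("k = %d exceeds number of videos (%d)", k, length(videoIds)),
         call. = FALSE)
  }
  shuffled <- withSeed(seed, sample(videoIds))
  assignment <- stats::setNames(
    as.integer(rep_len(seq_len(k), length(shuffled))), shuffled)[videoIds]
  names(assignment) <- videoIds
  new("FoldPlan", k = as.integer(k), assignment = assignment,
      seed = as.integer(seed))
}

#' Aggregate per-fold reports
#'
#' Sample mean and sample standard deviation (n-1 denominator) of
#' accuracy, weighted precision and weighted recall across folds.
#'
#' @param reports list of \linkS4class{EvalReport} (length >= 2).
#' @return data.frame with columns \code{metric}, \code{mean}, \code{sd}.
#' @export
aggregateFolds <- function(reports) {
  if (length(reports) < 2L) {
    stop("at least two fold reports are required", call. = FALSE)
  }
  M <- t(vapply(reports, metrics, numeric(3)))
  data.frame(metric = colnames(M),
             mean = colMeans(M),
             sd = apply(M, 2L, stats::sd),
             row.names = NULL)
}

#' Paired t-test on per-fold metrics
#'
#' Two-sided paired t-test on the differences d = a - b:
#' \code{t = mean(d) / (sd(d) / sqrt(n))}, p from Student's t with
#' n - 1 degrees of freedom. Zero-variance differences are flagged as
#' degenerate rather than producing a spurious statistic.
#'
#' @param a,b equal-length (>= 2) per-fold metric vectors from the two
#'   models evaluated on identical folds.
#' @param alpha significance level (default 0.05).
#' @return list with \code{t}, \code{p}, \code{df}, \code{significant},
#'   \code{degenerate}.
#' @export
pairedTTest <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) {
    stop("a and b must have equal length", call. = FALSE)
  }
  n <- length(a)
  if (n < 2L) stop("need at least two paired observations", call. = FALSE)
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    warning("zero-variance differences: paired t-test is degenerate")
    return(list(t = NA_real_, p = NA_real_, df = n - 1L,
                significant = NA, degenerate = TRUE))
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  list(t = tstat, p = p, df = n - 1L, significant = p < alpha,
       degenerate = FALSE)
}

#' Write an evaluation report as JSON
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output file.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(
    list(fold_id = report@foldId,
         accuracy = report@accuracy,
         weighted_precision = report@weightedPrecision,
         weighted_recall = report@weightedRecall,
         per_phase = report@perPhase,
         confusion = unname(apply(report@confusion, 1L, identity,
                                  simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
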