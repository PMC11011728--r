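test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusionMatrix(c(0L, 0L, 1L), c(0L, 1L, 1L), nClasses = 2L)
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  expect_equal(sum(cm), 3L)
  y <- sample(0:6, 50, replace = TRUE)
  cmp <- confusionMatrix(y, y)
  expect_equal(unname(diag(cmp)), unname(as.integer(table(factor(y, 0:6)))))
  expect_equal(sum(cmp) , 50L)
  expect_error(confusionMatrix(c(0L, 7L), c(0L, 0L)), "out of range")
})

test_that("classification metrics match hand computations", {
  perfect <- diag(c(3L, 2L, 5L))
  r <- classificationMetrics(perfect)
  expect_equal(r@accuracy, 1)
  expect_equal(r@weightedPrecision, 1)
  expect_equal(r@weightedRecall, 1)
  cm <- matrix(c(1L, 0L, 1L, 1L), 2, 2)   # rows true, cols pred
  r2 <- classificationMetrics(cm)
  expect_equal(r2@accuracy, 2 / 3, tolerance = 1e-12)
  expect_equal(r2@weightedRecall, (2 * 0.5 + 1 * 1) / 3, tolerance = 1e-12)
  # a class that is never predicted gets precision 0, with a warning
  cm0 <- matrix(c(2L, 1L, 0L, 0L), 2, 2)
  expect_warning(r3 <- classificationMetrics(cm0), "zero predicted")
  expect_equal(r3@perPhase$precision[2], 0)
  expect_error(classificationMetrics(matrix(0L, 3, 3)), "empty")
})

test_that("weighted recall equals accuracy on random confusion matrices", {
  set.seed(40)
  for (i in 1:100) {
    k <- sample(2:7, 1)
    cm <- matrix(rpois(k * k, 3), k, k)
    if (sum(cm) == 0) cm[1, 1] <- 1
    r <- suppressWarnings(classificationMetrics(cm))
    expect_equal(r@weightedRecall, r@accuracy, tolerance = 1e-12)
  }
})

test_that("k-fold plans partition whole videos into near-equal folds", {
  vids <- sprintf("v%02d", 1:10)
  plan <- kfoldSplit(vids, k = 5L, seed = 41L)
  a <- foldAssignment(plan)
  expect_setequal(names(a), vids)
  expect_equal(unname(table(a)), rep(2L, 5), ignore_attr = TRUE)
  expect_identical(a, foldAssignment(kfoldSplit(vids, 5L, seed = 41L)))
  expect_false(identical(a, foldAssignment(kfoldSplit(vids, 5L, seed = 42L))))
  # uneven case: sizes differ by at most one
  a2 <- foldAssignment(kfoldSplit(sprintf("v%02d", 1:11), 3L, seed = 1L))
  expect_lte(diff(range(table(a2))), 1L)
  expect_error(kfoldSplit(vids[1:3], k = 5L), "exceeds")
})

test_that("fold aggregation gives sample mean and n-1 standard deviation", {
  mk <- function(acc) {
    cm <- matrix(0L, 2, 2)
    cm[1, 1] <- as.integer(acc * 100)
    cm[2, 1] <- 100L - cm[1, 1]
    suppressWarnings(classificationMetrics(cm))
  }
  reps <- list(mk(0.8), mk(1.0))
  agg <- aggregateFolds(reps)
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, 0.9, tolerance = 1e-12)
  expect_equal(acc$sd, sd(c(0.8, 1.0)), tolerance = 1e-12)
  expect_equal(acc$sd, 0.1414214, tolerance = 1e-6)
  # identical reports -> zero sd; order invariance of the mean
  aggSame <- aggregateFolds(list(mk(0.9), mk(0.9), mk(0.9)))
  expect_true(all(aggSame$sd == 0))
  expect_equal(aggregateFolds(rev(reps))$mean, agg$mean)
  expect_error(aggregateFolds(reps[1]), "at least two")
})

test_that("paired t-test matches the closed form and stats::t.test", {
  a <- c(0.91, 0.92, 0.90, 0.93, 0.89)
  b <- c(0.88, 0.90, 0.86, 0.90, 0.87)
  res <- pairedTTest(a, b)
  d <- a - b
  tExp <- mean(d) / (sd(d) / sqrt(5))
  pExp <- 2 * pt(-abs(tExp), df = 4)
  expect_equal(res$t, tExp, tolerance = 1e-6)
  expect_equal(res$p, pExp, tolerance = 1e-6)
  # independent oracle: base R implementation
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_true(res$significant)
  # antisymmetry
  swap <- pairedTTest(b, a)
  expect_equal(swap$t, -res$t, tolerance = 1e-12)
  expect_equal(swap$p, res$p, tolerance = 1e-12)
})

test_that("degenerate paired differences are flagged, not mis-reported", {
  a <- c(0.91, 0.92, 0.90, 0.93, 0.89)
  expect_warning(res <- pairedTTest(a, a - 0.03), "degenerate")
  expect_true(res$degenerate)
  expect_true(is.na(res$t))
  expect_error(pairedTTest(a, a[1:3]), "equal length")
})

test_that("p-values shrink monotonically as the paired difference grows", {
  b <- c(0.88, 0.90, 0.86, 0.90, 0.87)
  noise <- c(0.001, -0.002, 0.002, -0.001, 0.001)
  res <- lapply(c(0.005, 0.01, 0.02, 0.05), function(delta) {
    pairedTTest(b + delta + noise, b)
  })
  ps <- vapply(res, `[[`, numeric(1), "p")
  ts <- vapply(res, `[[`, numeric(1), "t")
  expect_true(all(diff(abs(ts)) > 0))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("evaluation reports serialise to JSON", {
  cm <- diag(c(5L, 4L, 6L, 2L, 3L, 1L, 2L))
  r <- classificationMetrics(cm, foldId = 2L)
  path <- tempfile(fileext = ".json")
  writeEvalReport(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, 1)
  expect_equal(back$fold_id, 2L)
})
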