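test_that("cosine similarity matches closed-form cases", {
  expect_equal(cosineSimilarity(c(2, 3), c(2, 3)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 5)), 0)
  expect_equal(cosineSimilarity(c(1, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("contrastive loss equals a naive double-loop evaluation", {
  # independent oracle: literal transcription of the objective with loops
  naiveLoss <- function(X, Y, tau) {
    n <- nrow(X)
    total <- 0
    for (i in seq_len(n)) {
      num <- exp(cosineSimilarity(X[i, ], Y[i, ]) / tau)
      den <- 0
      for (j in seq_len(n)) {
        den <- den + exp(cosineSimilarity(X[i, ], Y[j, ]) / tau)
      }
      total <- total - log(num / den)
    }
    total / n
  }
  X <- matrix(c(1, 0, 2, 1, -1, 3), 3, 2)
  Y <- matrix(c(2, 1, 0, -1, 1, 1), 3, 2)
  expect_equal(multimodalContrastiveLoss(X, Y, tau = 1),
               naiveLoss(X, Y, 1), tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(2:8, 1); d <- sample(2:16, 1)
    tau <- sample(c(0.05, 0.1, 1), 1)
    X <- matrix(rnorm(n * d), n, d)
    Y <- matrix(rnorm(n * d), n, d)
    expect_equal(multimodalContrastiveLoss(X, Y, tau),
                 naiveLoss(X, Y, tau), tolerance = 1e-12)
    sym <- multimodalContrastiveLoss(X, Y, tau, symmetric = TRUE)
    expect_equal(sym, (naiveLoss(X, Y, tau) + naiveLoss(Y, X, tau)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("contrastive loss hits its analytic limits", {
  x <- matrix(c(1, 2, 3), 1, 3)
  expect_identical(multimodalContrastiveLoss(x, x), 0)
  # all similarities equal -> uniform softmax -> ln n
  Xc <- matrix(rep(c(1, 2), each = 5), 5, 2)
  expect_equal(multimodalContrastiveLoss(Xc, Xc, tau = 0.1), log(5),
               tolerance = 1e-12)
  expect_error(multimodalContrastiveLoss(matrix(0, 2, 2),
                                         matrix(1, 2, 2)), "zero-norm")
})

test_that("contrastive loss is invariant to pairing permutations and row scaling", {
  set.seed(22)
  X <- matrix(rnorm(12), 4, 3); Y <- matrix(rnorm(12), 4, 3)
  base <- multimodalContrastiveLoss(X, Y, 0.1)
  for (rep in 1:10) {
    p <- sample(4)
    expect_equal(multimodalContrastiveLoss(X[p, ], Y[p, ], 0.1), base,
                 tolerance = 1e-12)
    s <- runif(4, 0.1, 10)
    expect_equal(multimodalContrastiveLoss(X * s, Y, 0.1), base,
                 tolerance = 1e-12)
  }
  # raising a matched pair's similarity lowers the loss
  Y2 <- Y
  Y2[1, ] <- Y[1, ] + 0.5 * X[1, ] / sqrt(sum(X[1, ]^2))
  expect_lt(multimodalContrastiveLoss(X, Y2, 0.1), base)
})

test_that("analytic contrastive gradient matches finite differences", {
  set.seed(23)
  h <- 1e-6
  for (sym in c(FALSE, TRUE)) {
    X <- matrix(rnorm(12), 4, 3)
    Y <- matrix(rnorm(12), 4, 3)
    g <- contrastiveLossGrad(X, Y, tau = 0.1, symmetric = sym)
    for (i in seq_along(X)) {
      Xp <- X; Xp[i] <- Xp[i] + h
      Xm <- X; Xm[i] <- Xm[i] - h
      num <- (multimodalContrastiveLoss(Xp, Y, 0.1, sym) -
              multimodalContrastiveLoss(Xm, Y, 0.1, sym)) / (2 * h)
      expect_equal(g$dX[i], num, tolerance = 1e-5)
      Yp <- Y; Yp[i] <- Yp[i] + h
      Ym <- Y; Ym[i] <- Ym[i] - h
      num <- (multimodalContrastiveLoss(X, Yp, 0.1, sym) -
              multimodalContrastiveLoss(X, Ym, 0.1, sym)) / (2 * h)
      expect_equal(g$dY[i], num, tolerance = 1e-5)
    }
  }
})

test_that("NCE loss matches direct evaluation and its limits", {
  expect_equal(nceLoss(c(0.3, 0.7), c(0.3, 0.7), k = 1), log(2),
               tolerance = 1e-12)
  expect_equal(nceLoss(c(0.4, 0.9), c(0, 0), k = 3), 0)
  direct <- -mean(log(c(0.9 / (0.9 + 2 * 0.1), 0.5 / (0.5 + 2 * 0.5))))
  expect_equal(nceLoss(c(0.9, 0.5), c(0.1, 0.5), k = 2), direct,
               tolerance = 1e-12)
  expect_error(nceLoss(c(0, 1), c(0, 1), k = 1), "degenerate")
})

test_that("cross-entropy matches closed forms with 0-based labels", {
  expect_equal(crossEntropy(c(0, 1, 0), 1L), 0)
  expect_equal(crossEntropy(rep(1 / 7, 7), 3L), log(7), tolerance = 1e-12)
  expect_equal(crossEntropy(c(0.7, 0.2, 0.1), 1L), -log(0.2),
               tolerance = 1e-12)
  expect_error(crossEntropy(c(0.5, 0.2), 0L), "sum to 1")
  expect_error(crossEntropy(c(0.5, 0.5), 2L), "out of range")
  # epsilon floor keeps hard zeros finite
  expect_true(is.finite(crossEntropy(c(1, 0), 1L)))
})

test_that("learning-rate schedule ramps, peaks and anneals as specified", {
  spe <- 10L
  expect_equal(lrSchedule(0, 0.001, 5L, 50L, spe), 0)
  expect_equal(lrSchedule(5L * spe, 0.001, 5L, 50L, spe), 0.001)
  expect_equal(lrSchedule(50L * spe, 0.001, 5L, 50L, spe, floorLr = 0), 0,
               tolerance = 1e-15)
  mid <- (5L + (50L - 5L) / 2) * spe
  expect_equal(lrSchedule(mid, 0.001, 5L, 50L, spe), 0.0005,
               tolerance = 1e-12)
  # warmup is linear
  expect_equal(lrSchedule(25L, 0.001, 5L, 50L, spe), 0.001 * 25 / 50)
})
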