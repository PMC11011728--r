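test_that("sinusoidal positional encoding matches its closed form", {
  PE <- positionalEncoding(4L, 6L)
  expect_equal(PE[1, ], rep(c(0, 1), 3))          # sin 0, cos 0 alternating
  expect_equal(PE[2, 1], sin(1), tolerance = 1e-12)
  expect_equal(PE[2, 2], cos(1), tolerance = 1e-12)
  expect_equal(PE[3, 3], sin(2 / 10000^(2 / 6)), tolerance = 1e-12)
  expect_true(all(PE >= -1 & PE <= 1))
  expect_error(positionalEncoding(3L, 5L), "even")
})

test_that("self-attention matches a brute-force evaluation on a 2x2 case", {
  # independent oracle: explicit scalar arithmetic, no shared code path
  X <- matrix(c(1, 2, -1, 0.5), 2, 2)
  w <- list(Wq = matrix(c(1, 0, 0.5, -1), 2, 2),
            Wk = matrix(c(0, 1, 1, 0), 2, 2),
            Wv = matrix(c(2, -1, 0, 1), 2, 2),
            Wo = diag(2), bo = c(0.1, -0.2))
  Q <- X %*% w$Wq; K <- X %*% w$Wk; V <- X %*% w$Wv
  S <- Q %*% t(K) / sqrt(2)
  A <- matrix(0, 2, 2)
  for (i in 1:2) A[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
  expected <- A %*% V %*% w$Wo
  expected[, 1] <- expected[, 1] + 0.1
  expected[, 2] <- expected[, 2] - 0.2
  expect_equal(multiHeadSelfAttention(X, w, nHeads = 1L), expected,
               tolerance = 1e-12)
})

test_that("attention degenerates correctly for L = 1 and identical rows", {
  w <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2),
            Wo = matrix(c(1, 1, 0, 2), 2, 2), bo = c(0, 0))
  x <- matrix(c(3, -1), 1, 2)
  # L = 1: softmax of a scalar is 1, output = V row through Wo
  expect_equal(multiHeadSelfAttention(x, w, 1L), x %*% w$Wo,
               tolerance = 1e-12)
  # identical rows in, identical rows out
  X <- matrix(rep(c(0.3, 0.7), each = 4), 4, 2)
  out <- multiHeadSelfAttention(X, w, 2L)
  expect_equal(out[1, ], out[4, ], tolerance = 1e-12)
})

test_that("attention rows are a probability distribution", {
  set.seed(11)
  cfgw <- PhaseFusion:::withSeed(11, PhaseFusion:::initBlockWeights(8L, 16L))
  X <- matrix(rnorm(40), 5, 8)
  out <- multiHeadSelfAttention(X, cfgw$att, nHeads = 2L,
                                returnAttention = TRUE)
  for (A in attr(out, "attention")) {
    expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-12)
    expect_true(all(A >= 0))
  }
})

test_that("encoder output is deterministic with pooled = positional mean", {
  cfg <- encoderConfig(nLayers = 2L, dModel = 8L, nHeads = 2L, dFf = 16L,
                       seed = 12L)
  w <- initEncoderWeights(cfg)
  set.seed(13)
  X <- matrix(rnorm(4 * 8), 4, 8)
  out <- encodeSequence(X, cfg, w)
  expect_identical(out$hidden, encodeSequence(X, cfg, w)$hidden)
  expect_equal(out$pooled, colMeans(out$hidden), tolerance = 1e-12)
  expect_error(encodeSequence(matrix(0, 2, 6), cfg, w), "does not match")
  expect_error(encodeSequence(matrix(NaN, 2, 8), cfg, w), "non-finite")
})

test_that("zeroed sublayer output projections reduce a block to layer norm", {
  cfg <- encoderConfig(nLayers = 1L, dModel = 8L, nHeads = 2L, dFf = 16L,
                       seed = 14L)
  w <- initEncoderWeights(cfg)
  w$b1$att$Wo[] <- 0; w$b1$att$bo[] <- 0
  w$b1$ffn$W2[] <- 0; w$b1$ffn$b2[] <- 0
  set.seed(15)
  X <- matrix(rnorm(3 * 8), 3, 8)
  out <- encodeSequence(X, cfg, w)
  Z <- X + positionalEncoding(3L, 8L)
  ln <- function(M) {
    t(apply(M, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  }
  expect_equal(out$hidden, ln(ln(Z)), tolerance = 1e-10)
})

test_that("encoder stays finite over many random seeded inputs", {
  cfg <- encoderConfig(nLayers = 1L, dModel = 8L, nHeads = 2L, dFf = 16L,
                       seed = 16L)
  w <- initEncoderWeights(cfg)
  set.seed(17)
  ok <- TRUE
  for (i in seq_len(1000)) {
    X <- matrix(rnorm(4 * 8, sd = runif(1, 0.1, 10)), 4, 8)
    out <- encodeSequence(X, cfg, w)
    ok <- ok && all(is.finite(out$hidden)) && all(is.finite(out$pooled))
  }
  expect_true(ok)
})

test_that("single-tower forward concatenates image-first and pools", {
  cfg <- encoderConfig(nLayers = 1L, dModel = 8L, nHeads = 2L, dFf = 16L,
                       seed = 18L)
  w <- initEncoderWeights(cfg)
  set.seed(19)
  img <- matrix(rnorm(3 * 8), 3, 8)
  txt <- matrix(rnorm(2 * 8), 2, 8)
  pooled <- singleTowerForward(img, txt, cfg, w)
  full <- encodeSequence(rbind(img, txt), cfg, w)
  expect_equal(pooled, full$pooled, tolerance = 1e-12)
  expect_equal(nrow(full$hidden), 5L)
  expect_error(singleTowerForward(img, matrix(0, 2, 6), cfg, w), "differ")
})

test_that("encoder weight checkpoints survive a bit-exact round trip", {
  vocab <- buildVocab(c("calot triangle dissection"))
  cfg <- tinyModelConfig()
  model <- initPhaseModel(vocab, cfg, seed = 20L)
  prefix <- tempfile()
  saveModel(model, prefix)
  back <- loadModel(prefix)
  expect_identical(modelWeights(back), modelWeights(model))
  expect_identical(back@vocab, model@vocab)
  expect_identical(back@mode, model@mode)
})
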