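test_that("patchify produces row-major patches that conserve the pixels", {
  set.seed(1)
  frame <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  P <- patchify(frame, 8L)
  expect_equal(dim(P), c(16L, 8 * 8 * 3))
  expect_equal(sum(P), sum(frame))                      # permutation
  expect_equal(unpatchify(P, 32, 32, 3, 8L), frame)     # exact inverse
  # first patch is the top-left corner block
  expect_equal(P[1, ], as.vector(frame[1:8, 1:8, ]))
  # second patch moves right along the row (row-major order)
  expect_equal(P[2, ], as.vector(frame[1:8, 9:16, ]))
})

test_that("patchify rejects non-divisible frames, naming the axis", {
  frame <- array(0, dim = c(24, 32, 3))
  expect_error(patchify(frame, 16L), "height")
  frame2 <- array(0, dim = c(32, 24, 3))
  expect_error(patchify(frame2, 16L), "width")
})

test_that("image tower output matches the hand-evaluated single-patch case", {
  # one patch (H = W = P), zero tower blocks: the embedding is the
  # linear projection of the flattened patch plus the position-0 encoding
  tc <- towerConfig(dOut = 4L, patchSize = 4L, nBlocks = 0L, nHeads = 2L,
                    seed = 2L)
  w <- initImageTower(tc, frameSize = 4L)
  set.seed(3)
  frame <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  v <- as.vector(frame)
  expected <- drop(v %*% w$proj$W) + w$proj$b + positionalEncoding(1, 4)[1, ]
  expect_equal(embedImage(frame, tc, w), expected, tolerance = 1e-12)
})

test_that("zero projection with positional encoding off embeds to zero", {
  tc <- towerConfig(dOut = 4L, patchSize = 4L, nBlocks = 0L, nHeads = 2L,
                    usePositional = FALSE)
  w <- initImageTower(tc, frameSize = 8L)
  w$proj$W[] <- 0; w$proj$b[] <- 0
  frame <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  expect_equal(embedImage(frame, tc, w), numeric(4))
})

test_that("image embedding is deterministic and Lipschitz in the frame", {
  tc <- towerConfig(dOut = 8L, patchSize = 4L, nBlocks = 1L, nHeads = 2L,
                    dFf = 16L, seed = 4L)
  w <- initImageTower(tc, frameSize = 8L)
  set.seed(5)
  frame <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  e1 <- embedImage(frame, tc, w)
  expect_identical(e1, embedImage(frame, tc, w))
  # single-pixel perturbations change the output by O(eps)
  for (eps in c(1e-4, 1e-5)) {
    f2 <- frame
    f2[3, 5, 2] <- f2[3, 5, 2] + eps
    delta <- sqrt(sum((embedImage(f2, tc, w) - e1)^2))
    expect_lt(delta, 100 * eps)
  }
})

test_that("vocabulary orders by frequency then lexicographically", {
  vocab <- buildVocab(c("a b", "a"), minCount = 1L)
  expect_equal(vocab[["<pad>"]], 1L)
  expect_equal(vocab[["<unk>"]], 2L)
  expect_equal(vocab[["a"]], 3L)   # most frequent gets lowest free id
  expect_equal(vocab[["b"]], 4L)
  expect_identical(vocab, buildVocab(c("a b", "a"), minCount = 1L))
  expect_error(buildVocab(character()), "non-empty")
  # ties broken lexicographically
  v2 <- buildVocab(c("zeta alpha"), minCount = 1L)
  expect_lt(v2[["alpha"]], v2[["zeta"]])
})

test_that("tokens below minCount collapse to the unknown id", {
  vocab <- buildVocab(c("common common rare"), minCount = 2L)
  expect_false("rare" %in% names(vocab))
  ids <- tokenIds("common rare", vocab)
  expect_equal(ids, c(vocab[["common"]], vocab[["<unk>"]]))
})

test_that("text embedding follows lookup + positional encoding rules", {
  vocab <- buildVocab(c("cystic duct artery"))
  tc <- towerConfig(dOut = 8L, nHeads = 2L, seed = 6L)
  w <- initTextTower(tc, vocab)
  # single token: embedding row plus position-0 encoding
  E <- embedText("duct", vocab, tc, w)
  expect_equal(dim(E), c(1L, 8L))
  expect_equal(E[1, ], w$emb[vocab[["duct"]], ] + positionalEncoding(1, 8)[1, ])
  # unknown tokens collapse: two texts differing only in OOV words agree
  expect_equal(embedText("duct qqq", vocab, tc, w),
               embedText("duct zzz", vocab, tc, w))
  # trailing whitespace is ignored
  expect_equal(embedText("cystic duct  ", vocab, tc, w),
               embedText("cystic duct", vocab, tc, w))
  # empty text maps to the single padding token
  expect_equal(nrow(embedText("", vocab, tc, w)), 1L)
})

test_that("precomputed embedding tables round-trip through TSV", {
  set.seed(8)
  tab <- list(f1 = matrix(rnorm(12), 3, 4), f2 = matrix(rnorm(8), 2, 4))
  path <- tempfile(fileext = ".tsv")
  writePrecomputedEmbeddings(tab, path)
  back <- loadPrecomputedEmbeddings(path)
  expect_equal(back, tab, tolerance = 1e-12)
  # ragged dimensions are a format error
  lines <- readLines(path)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c(lines[1], "f1\t0\t1\t2\t\t"), bad)
  expect_error(loadPrecomputedEmbeddings(bad), "dimensions")
  # empty table round trip
  empty <- tempfile(fileext = ".tsv")
  writePrecomputedEmbeddings(list(), empty)
  expect_identical(loadPrecomputedEmbeddings(empty), list())
  expect_error(loadPrecomputedEmbeddings(tempfile()), "not found")
})
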