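test_that("phase catalog carries the seven phases in procedural order", {
  cat7 <- fixtureCatalog()
  ph <- phaseTable(cat7)
  expect_equal(nrow(ph), 7L)
  expect_equal(ph$phase_id, 0:6)
  expect_equal(ph$name[1], "preparation")
  # published duration statistics for the Calot's triangle dissection
  expect_equal(ph$duration_mean[2], 954)
  expect_equal(ph$duration_sd[2], 538)
  expect_equal(anyDuplicated(ph$canonical_text), 0L)
  expect_error(buildPhaseCatalog("nonexistent"), "unknown motif scheme")
})

test_that("duration sampler is gamma moment-matched, positive, seeded", {
  cat7 <- fixtureCatalog()
  d <- samplePhaseDurations(cat7, 0L, 1e5, seed = 123)
  expect_true(all(d > 0))
  # Preparation: 125 +/- 95; MC standard error of the mean = 95/sqrt(1e5)
  expect_lt(abs(mean(d) - 125), 4 * 95 / sqrt(1e5))
  expect_identical(d, samplePhaseDurations(cat7, 0L, 1e5, seed = 123))
  expect_error(samplePhaseDurations(cat7, 9L, 10), "invalid phase_id")
  expect_error(samplePhaseDurations(cat7, 0L, 0), "positive count")
})

test_that("gamma moment-matching recovers Calot-phase mean and sd at large n", {
  # shape = (954/538)^2, scale = 538^2/954; independent oracle: draw from
  # stats::rgamma with those parameters directly and compare moments.
  shape <- (954 / 538)^2
  scale <- 538^2 / 954
  expect_equal(shape * scale, 954)
  expect_equal(sqrt(shape) * scale, 538)
  cat7 <- fixtureCatalog()
  n <- 1e5
  d <- samplePhaseDurations(cat7, 1L, n, seed = 99)
  seMean <- 538 / sqrt(n)
  # SE of the sd for a gamma via the kurtosis: var(s^2) ~ (k-1+2)/n * sd^4
  kurt <- 3 + 6 / shape
  seSd <- 538 * sqrt((kurt - 1) / (4 * n))
  expect_lt(abs(mean(d) - 954), 4 * seMean)
  expect_lt(abs(sd(d) - 538), 4 * seSd)
})

test_that("frame rendering is deterministic, bounded, and phase-discriminative", {
  cat7 <- fixtureCatalog()
  f0 <- renderFrame(cat7, 0L, noiseLevel = 0, size = 32L)
  expect_identical(f0, renderFrame(cat7, 0L, noiseLevel = 0, size = 32L))
  f1 <- renderFrame(cat7, 1L, noiseLevel = 0, size = 32L)
  expect_gt(mean(abs(f0 - f1)), 0)
  fn <- renderFrame(cat7, 3L, noiseLevel = 0.3, tools = TRUE, smoke = TRUE,
                    size = 32L, seed = 5)
  expect_true(all(fn >= 0 & fn <= 1))
  expect_identical(fn, renderFrame(cat7, 3L, noiseLevel = 0.3, tools = TRUE,
                                   smoke = TRUE, size = 32L, seed = 5))
  expect_error(renderFrame(cat7, 0L, noiseLevel = -1), "non-negative")
})

test_that("text composition keeps the canonical form and the phase keyword", {
  cat7 <- fixtureCatalog()
  ph <- phaseTable(cat7)
  for (p in 0:6) {
    expect_identical(composeText(cat7, p, variability = 0),
                     ph$canonical_text[p + 1])
    txt <- composeText(cat7, p, variability = 1, seed = 42)
    expect_match(txt, ph$keyword[p + 1], fixed = TRUE)
    expect_identical(txt, composeText(cat7, p, variability = 1, seed = 42))
  }
})

test_that("generated videos traverse all 7 phases contiguously in order", {
  mf <- fixtureDataset(nVideos = 2L, fps = 0.2, seed = 3L)
  rec <- manifestRecords(mf)
  for (v in unique(rec$video_id)) {
    ph <- rec$phase_id[rec$video_id == v]
    expect_true(all(diff(ph) >= 0))           # non-decreasing
    expect_setequal(unique(ph), 0:6)          # covers all phases
    expect_equal(length(rle(ph)$values), 7L)  # one contiguous run each
  }
  # every stored path resolves and frames load in [0,1]
  fr <- loadFrames(mf, rows = 1:2)
  expect_true(all(vapply(fr, function(f) all(f >= 0 & f <= 1), logical(1))))
})

test_that("regeneration with the same seed is byte-identical", {
  d1 <- tempfile(); d2 <- tempfile()
  generateDataset(2L, fps = 0.05, seed = 17L, outDir = d1)
  generateDataset(2L, fps = 0.05, seed = 17L, outDir = d2)
  m1 <- readLines(file.path(d1, "manifest.csv"))
  m2 <- readLines(file.path(d2, "manifest.csv"))
  expect_identical(m1, m2)
  # frame files byte-identical
  f1 <- list.files(d1, pattern = "png$", recursive = TRUE)
  f2 <- list.files(d2, pattern = "png$", recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1[seq_len(min(5, length(f1)))]) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("default split reproduces the 50/80 train fraction", {
  mf <- fixtureDataset(nVideos = 8L, fps = 0.01, seed = 5L)
  sp <- manifestSplit(mf)
  expect_equal(sum(sp$partition == "train"), 5L)  # round(8 * 50/80)
  expect_equal(sum(sp$partition == "test"), 3L)
})

test_that("zero-noise motifs are nearest-centroid separable", {
  cat7 <- fixtureCatalog()
  centroids <- sapply(0:6, function(p) {
    as.vector(renderFrame(cat7, p, noiseLevel = 0, size = 32L))
  })
  # a fresh motif render must match its own phase centroid exactly
  for (p in 0:6) {
    x <- as.vector(renderFrame(cat7, p, noiseLevel = 0, size = 32L))
    d2 <- colSums((centroids - x)^2)
    expect_equal(which.min(d2) - 1L, p)
  }
  # and with mild noise the centroid classifier still recovers the phase
  set.seed(31)
  for (p in 0:6) {
    x <- as.vector(renderFrame(cat7, p, noiseLevel = 0.05, size = 32L))
    expect_equal(which.min(colSums((centroids - x)^2)) - 1L, p)
  }
})

test_that("manifest round-trips through CSV + JSON sidecar", {
  mf <- fixtureDataset(nVideos = 2L, fps = 0.05, seed = 23L)
  mf2 <- readManifest(mf@dir)
  expect_equal(manifestRecords(mf2), manifestRecords(mf))
  expect_equal(manifestSplit(mf2), manifestSplit(mf))
  expect_equal(mf2@seed, mf@seed)
})
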