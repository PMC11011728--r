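# Shared fixtures, built in code and cached for the test run.

.fixtureCache <- new.env(parent = emptyenv())

fixtureCatalog <- function() {
  if (is.null(.fixtureCache$catalog)) {
    .fixtureCache$catalog <- buildPhaseCatalog()
  }
  .fixtureCache$catalog
}

# A small generated dataset, cached by its parameter signature.
fixtureDataset <- function(nVideos = 4L, fps = 0.015, seed = 7L,
                           noiseLevel = 0.05, variability = 0.3,
                           toolProb = 0.3, smokeProb = 0.2) {
  key <- paste(nVideos, fps, seed, noiseLevel, variability,
               toolProb, smokeProb, sep = "_")
  if (is.null(.fixtureCache[[key]])) {
    .fixtureCache[[key]] <- generateDataset(
      nVideos = nVideos, fps = fps, seed = seed, noiseLevel = noiseLevel,
      variability = variability, toolProb = toolProb, smokeProb = smokeProb,
      outDir = file.path(tempdir(), paste0("pf_fix_", key)))
  }
  .fixtureCache[[key]]
}

# Desk-scale structural config shrunk further for unit tests.
tinyModelConfig <- function(frameSize = 32L) {
  modelConfigList(
    tower = towerConfig(dOut = 16L, patchSize = 8L, nBlocks = 1L,
                        nHeads = 2L, dFf = 32L),
    encoder = encoderConfig(nLayers = 1L, dModel = 16L, nHeads = 2L,
                            dFf = 32L),
    mlpHidden = 32L, frameSize = frameSize)
}
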