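# Synthetic seven-phase laparoscopic dataset generator.
#
# Emulates the structure of public cholecystectomy video collections:
# seven ordered surgical phases with published per-phase duration
# statistics (mean +/- sd, seconds), frames degraded by instrument
# overlays, smoke and sensor noise, and a short text description paired
# with every frame.

# Published per-phase duration statistics (seconds).
.phaseDurations <- data.frame(
  phase_id = 0:6,
  name = c("preparation",
           "calot triangle dissection",
           "clipping and cutting",
           "gallbladder dissection",
           "gallbladder packaging",
           "cleaning and coagulation",
           "gallbladder retraction"),
  duration_mean = c(125, 954, 168, 857, 98, 178, 83),
  duration_sd   = c(95, 538, 152, 551, 53, 166, 56),
  stringsAsFactors = FALSE
)

# One unique keyword token per phase; every generated text contains it.
.phaseKeywords <- c("preparation", "calot", "clipping", "liver",
                    "packaging", "coagulation", "retraction")

.phaseTexts <- c(
  "preparation of the operative field before any instrument is inserted",
  "dissection of the calot triangle exposing the cystic duct and artery",
  "clipping and cutting of the cystic duct and the cystic artery",
  "dissection detaching the gallbladder from the liver bed",
  "packaging of the resected gallbladder into a specimen bag",
  "coagulation and cleaning of the operative area after dissection",
  "retraction of the bagged gallbladder out through the trocar"
)

# Deterministic per-phase image motifs: base tissue hue plus a
# phase-specific arrangement of elliptical structures. Coordinates are
# fractions of the frame side so any frame size renders consistently.
.defaultMotifs <- function() {
  mk <- function(base, ellipses) list(base = base, ellipses = ellipses)
  el <- function(cx, cy, rx, ry, col) {
    list(cx = cx, cy = cy, rx = rx, ry = ry, col = col)
  }
  list(
    mk(c(0.45, 0.20, 0.18), list(
      el(0.50, 0.55, 0.30, 0.22, c(0.75, 0.45, 0.40)))),
    mk(c(0.55, 0.25, 0.15), list(
      el(0.35, 0.40, 0.18, 0.12, c(0.90, 0.75, 0.30)),
      el(0.65, 0.60, 0.15, 0.22, c(0.70, 0.30, 0.25)))),
    mk(c(0.50, 0.30, 0.25), list(
      el(0.30, 0.30, 0.10, 0.10, c(0.85, 0.85, 0.90)),
      el(0.70, 0.30, 0.10, 0.10, c(0.85, 0.85, 0.90)),
      el(0.50, 0.70, 0.25, 0.12, c(0.60, 0.25, 0.20)))),
    mk(c(0.40, 0.28, 0.12), list(
      el(0.50, 0.35, 0.32, 0.18, c(0.45, 0.60, 0.30)),
      el(0.50, 0.72, 0.28, 0.12, c(0.55, 0.20, 0.15)))),
    mk(c(0.35, 0.30, 0.35), list(
      el(0.50, 0.50, 0.22, 0.30, c(0.30, 0.45, 0.75)))),
    mk(c(0.55, 0.35, 0.20), list(
      el(0.30, 0.60, 0.20, 0.14, c(0.95, 0.60, 0.50)),
      el(0.70, 0.40, 0.12, 0.20, c(0.35, 0.55, 0.70)),
      el(0.50, 0.20, 0.16, 0.08, c(0.80, 0.80, 0.35)))),
    mk(c(0.30, 0.22, 0.28), list(
      el(0.50, 0.50, 0.10, 0.38, c(0.25, 0.60, 0.45)),
      el(0.50, 0.18, 0.20, 0.08, c(0.75, 0.70, 0.65))))
  )
}

#' Build the seven-phase catalog
#'
#' Returns the ordered catalog of the seven laparoscopic cholecystectomy
#' phases, carrying the published per-phase duration statistics (mean and
#' standard deviation, in seconds), one canonical text description per
#' phase, and the rendering parameters of the phase's synthetic motif.
#'
#' @param motifScheme name of a registered rendering scheme. Only
#'   \code{"default"} is registered.
#' @return a \linkS4class{PhaseCatalog}.
#' @examples
#' cat7 <- buildPhaseCatalog()
#' phaseTable(cat7)
#' @export
buildPhaseCatalog <- function(motifScheme = "default") {
  if (!identical(motifScheme, "default")) {
    stop(sprintf("unknown motif scheme '%s'", motifScheme), call. = FALSE)
  }
  ph <- .phaseDurations
  ph$canonical_text <- .phaseTexts
  ph$keyword <- .phaseKeywords
  new("PhaseCatalog", phases = ph, motifParams = .defaultMotifs(),
      motifScheme = motifScheme)
}

.checkPhaseId <- function(catalog, phaseId) {
  if (length(phaseId) != 1L || is.na(phaseId) ||
      !phaseId %in% catalog@phases$phase_id) {
    stop(sprintf("invalid phase_id: %s", paste(phaseId, collapse = ",")),
         call. = FALSE)
  }
  as.integer(phaseId)
}

#' Sample phase durations
#'
#' Draws phase durations (seconds) from a gamma distribution
#' moment-matched to the catalog's (mean, sd) for the phase:
#' shape = mean^2/sd^2, scale = sd^2/mean. The gamma law keeps durations
#' strictly positive while recovering both published moments exactly in
#' expectation.
#'
#' @param catalog a \linkS4class{PhaseCatalog}.
#' @param phaseId integer phase id in 0..6.
#' @param n number of draws (>= 1).
#' @param seed integer seed; identical seeds give identical draws.
#' @return numeric vector of n strictly positive durations in seconds.
#' @examples
#' cat7 <- buildPhaseCatalog()
#' mean(samplePhaseDurations(cat7, 0, 1000, seed = 1))
#' @export
samplePhaseDurations <- function(catalog, phaseId, n, seed = NULL) {
  phaseId <- .checkPhaseId(catalog, phaseId)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  row <- catalog@phases[catalog@phases$phase_id == phaseId, ]
  shape <- row$duration_mean^2 / row$duration_sd^2
  scale <- row$duration_sd^2 / row$duration_mean
  withSeed(seed, stats::rgamma(as.integer(n), shape = shape, scale = scale))
}

.ellipseMask <- function(X, Y, e) {
  ((X - e$cx) / e$rx)^2 + ((Y - e$cy) / e$ry)^2 <= 1
}

#' Render one synthetic frame
#'
#' Produces a deterministic phase-specific motif (base tissue hue plus a
#' phase-dependent arrangement of ellipses), optionally degraded by the
#' nuisance factors that affect real laparoscopic video: bright
#' instrument shafts (line segments), low-frequency smoke brightening,
#' and additive Gaussian sensor noise. Values are clipped to [0, 1].
#'
#' Tool and smoke placement and the noise field consume the current RNG
#' stream (or \code{seed} if given); with \code{noiseLevel = 0} and both
#' nuisance flags off, the frame is a pure function of the phase.
#'
#' @param catalog a \linkS4class{PhaseCatalog}.
#' @param phaseId integer phase id in 0..6.
#' @param noiseLevel standard deviation of additive Gaussian noise (>= 0).
#' @param tools logical; overlay 1-2 bright instrument lines.
#' @param smoke logical; add a low-frequency brightening blob.
#' @param size frame side length in pixels (frames are size x size x 3).
#' @param seed optional integer seed for the nuisance/noise draws.
#' @return a size x size x 3 array with values in [0, 1].
#' @export
renderFrame <- function(catalog, phaseId, noiseLevel = 0, tools = FALSE,
                        smoke = FALSE, size = 64L, seed = NULL) {
  phaseId <- .checkPhaseId(catalog, phaseId)
  if (noiseLevel < 0) stop("noiseLevel must be non-negative", call. = FALSE)
  motif <- catalog@motifParams[[phaseId + 1L]]
  H <- as.integer(size)
  u <- (seq_len(H) - 0.5) / H
  X <- matrix(u, H, H, byrow = TRUE)   # column coordinate
  Y <- matrix(u, H, H)                 # row coordinate
  shade <- 0.55 + 0.35 * Y             # vertical illumination gradient
  frame <- array(0, dim = c(H, H, 3L))
  for (c in 1:3) frame[, , c] <- motif$base[c] * shade
  for (e in motif$ellipses) {
    m <- .ellipseMask(X, Y, e)
    for (c in 1:3) {
      ch <- frame[, , c]
      ch[m] <- 0.25 * ch[m] + 0.75 * e$col[c]
      frame[, , c] <- ch
    }
  }
  withSeed(seed, {
    if (isTRUE(tools)) {
      nLines <- sample(1:2, 1L)
      for (i in seq_len(nLines)) {
        p0 <- stats::runif(2)
        p1 <- stats::runif(2)
        # distance from each pixel to the segment p0-p1, in side units
        dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
        len2 <- max(dx^2 + dy^2, 1e-8)
        t <- pmin(pmax(((X - p0[1]) * dx + (Y - p0[2]) * dy) / len2, 0), 1)
        d2 <- (X - (p0[1] + t * dx))^2 + (Y - (p0[2] + t * dy))^2
        m <- d2 <= (1.5 / H)^2
        toolCol <- c(0.92, 0.92, 0.96)
        for (c in 1:3) {
          ch <- frame[, , c]
          ch[m] <- toolCol[c]
          frame[, , c] <- ch
        }
      }
    }
    if (isTRUE(smoke)) {
      cx <- stats::runif(1); cy <- stats::runif(1)
      sigma <- 0.5
      blob <- 0.25 * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sigma^2))
      for (c in 1:3) frame[, , c] <- frame[, , c] + blob
    }
    if (noiseLevel > 0) {
      frame <- frame + array(stats::rnorm(length(frame), sd = noiseLevel),
                             dim = dim(frame))
    }
  })
  frame[frame < 0] <- 0
  frame[frame > 1] <- 1
  frame
}

.textVariants <- function(canonical) {
  c(paste("view showing", canonical),
    paste("the surgeon performs", canonical),
    paste(canonical, "in progress"),
    paste("laparoscopic scene with", canonical))
}

#' Compose the text paired with a frame
#'
#' Returns the phase's canonical description when \code{variability} is
#' zero; otherwise, with probability \code{variability}, a template
#' variant (prefix/suffix jitter) that always retains the phase's
#' keyword token.
#'
#' @param catalog a \linkS4class{PhaseCatalog}.
#' @param phaseId integer phase id in 0..6.
#' @param variability probability in [0, 1] of emitting a variant.
#' @param seed optional integer seed.
#' @return a character scalar containing the phase keyword.
#' @export
composeText <- function(catalog, phaseId, variability = 0, seed = NULL) {
  phaseId <- .checkPhaseId(catalog, phaseId)
  stopifnot(variability >= 0, variability <= 1)
  canonical <- catalog@phases$canonical_text[phaseId + 1L]
  if (variability == 0) return(canonical)
  withSeed(seed, {
    if (stats::runif(1) < variability) {
      sample(.textVariants(canonical), 1L)
    } else canonical
  })
}

#' Generate a synthetic seven-phase dataset
#'
#' Each synthetic video runs through the seven phases in procedural
#' order; a gamma-distributed duration is drawn per phase and converted
#' to \code{round(duration * fps)} frames (minimum 1). Every frame gets
#' a paired text via \code{\link{composeText}} and nuisance factors
#' (instrument lines, smoke) drawn independently per frame. Videos are
#' split whole into train/test at \code{splitFraction} (default 50/80,
#' the published train/test ratio). Frames are written as PNG, the
#' manifest as CSV (\code{video_id,frame_index,path,phase_id,text}) and
#' the generator parameters as a JSON sidecar.
#'
#' Identical \code{(seed, parameters)} regenerate byte-identical
#' manifests and frames.
#'
#' @param nVideos number of synthetic videos (>= 1).
#' @param fps frames per second of the sampling grid (> 0).
#' @param catalog a \linkS4class{PhaseCatalog}.
#' @param noiseLevel additive Gaussian noise sd (default 0.05).
#' @param variability text-variant probability in [0, 1] (default 0.3).
#' @param toolProb per-frame probability of instrument overlay (default 0.3).
#' @param smokeProb per-frame probability of smoke (default 0.2).
#' @param imageSize frame side length in pixels (default 64).
#' @param splitFraction fraction of videos assigned to training
#'   (default 50/80).
#' @param seed integer master seed.
#' @param outDir output directory (created if missing).
#' @return a \linkS4class{DatasetManifest}.
#' @examples
#' cat7 <- buildPhaseCatalog()
#' mf <- generateDataset(2, fps = 0.02, cat7, seed = 1, outDir = tempfile())
#' head(manifestRecords(mf))
#' @export
generateDataset <- function(nVideos, fps, catalog = buildPhaseCatalog(),
                            noiseLevel = 0.05, variability = 0.3,
                            toolProb = 0.3, smokeProb = 0.2,
                            imageSize = 64L, splitFraction = 50 / 80,
                            seed = 1L, outDir = tempfile("phasefusion_")) {
  stopifnot(nVideos >= 1, fps > 0)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", outDir), call. = FALSE)
  }
  params <- list(nVideos = as.integer(nVideos), fps = fps,
                 noiseLevel = noiseLevel, variability = variability,
                 toolProb = toolProb, smokeProb = smokeProb,
                 imageSize = as.integer(imageSize),
                 splitFraction = splitFraction,
                 motifScheme = catalog@motifScheme)
  phases <- catalog@phases
  recs <- withSeed(childSeed(seed, "datagen"), {
    out <- vector("list", nVideos)
    for (v in seq_len(nVideos)) {
      vid <- sprintf("v%03d", v)
      vdir <- file.path(outDir, vid)
      dir.create(vdir, showWarnings = FALSE)
      fi <- 0L
      rows <- list()
      for (p in phases$phase_id) {
        dur <- stats::rgamma(1,
          shape = phases$duration_mean[p + 1L]^2 / phases$duration_sd[p + 1L]^2,
          scale = phases$duration_sd[p + 1L]^2 / phases$duration_mean[p + 1L])
        nFrames <- max(1L, as.integer(round(dur * fps)))
        for (f in seq_len(nFrames)) {
          tools <- stats::runif(1) < toolProb
          smoke <- stats::runif(1) < smokeProb
          frame <- renderFrame(catalog, p, noiseLevel = noiseLevel,
                               tools = tools, smoke = smoke,
                               size = imageSize)
          txt <- composeText(catalog, p, variability = variability)
          rel <- file.path(vid, sprintf("f%05d.png", fi))
          png::writePNG(frame, file.path(outDir, rel))
          rows[[length(rows) + 1L]] <- data.frame(
            video_id = vid, frame_index = fi, path = rel,
            phase_id = p, text = txt, stringsAsFactors = FALSE)
          fi <- fi + 1L
        }
      }
      out[[v]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  })
  rownames(recs) <- NULL
  vids <- sprintf("v%03d", seq_len(nVideos))
  nTrain <- max(1L, min(nVideos - 1L, as.integer(round(nVideos * splitFraction))))
  if (nVideos == 1L) nTrain <- 1L
  shuffled <- withSeed(childSeed(seed, "folds"), sample(vids))
  split <- data.frame(video_id = vids,
                      partition = ifelse(vids %in% shuffled[seq_len(nTrain)],
                                         "train", "test"),
                      stringsAsFactors = FALSE)
  mf <- new("DatasetManifest", records = recs, split = split,
            seed = as.integer(seed), generatorParams = params, dir = outDir)
  writeManifest(mf)
  mf
}

#' Write a manifest to its directory
#'
#' Writes \code{manifest.csv} (header
#' \code{video_id,frame_index,path,phase_id,text}) and a
#' \code{params.json} sidecar holding seed, generator parameters and the
#' train/test split.
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @return the manifest, invisibly.
#' @export
writeManifest <- function(manifest) {
  utils::write.csv(manifest@records,
                   file.path(manifest@dir, "manifest.csv"),
                   row.names = FALSE)
  side <- list(seed = manifest@seed,
               generator_params = manifest@generatorParams,
               split = manifest@split)
  jsonlite::write_json(side, file.path(manifest@dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a manifest back from a dataset directory
#'
#' @param dir directory containing \code{manifest.csv} and
#'   \code{params.json}.
#' @return a \linkS4class{DatasetManifest}.
#' @export
readManifest <- function(dir) {
  csv <- file.path(dir, "manifest.csv")
  if (!file.exists(csv)) stop(sprintf("no manifest.csv in '%s'", dir),
                              call. = FALSE)
  recs <- utils::read.csv(csv, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  new("DatasetManifest", records = recs,
      split = as.data.frame(side$split, stringsAsFactors = FALSE),
      seed = as.integer(side$seed), generatorParams = as.list(side$generator_params),
      dir = dir)
}

#' Load all frames referenced by a manifest
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param rows optional integer subset of record rows.
#' @return list of H x W x 3 arrays, one per (selected) record, in
#'   record order.
#' @export
loadFrames <- function(manifest, rows = NULL) {
  rec <- manifest@records
  if (!is.null(rows)) rec <- rec[rows, , drop = FALSE]
  lapply(rec$path, function(p) {
    fp <- file.path(manifest@dir, p)
    if (!file.exists(fp)) stop(sprintf("frame not found: %s", fp), call. = FALSE)
    fr <- png::readPNG(fp)
    if (length(dim(fr)) == 2L) fr <- array(rep(fr, 3L), dim = c(dim(fr), 3L))
    fr
  })
}
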