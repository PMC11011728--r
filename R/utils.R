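# Internal numerical helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All seeded package entry points funnel through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage child seed from a master seed; keeps every stage's
# randomness independent yet reproducible, and below .Machine$integer.max.
childSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(datagen = 101L, towers = 211L, classifier = 307L,
               folds = 401L, onetower = 503L, eval = 601L, misc = 701L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629) + 1L
}

# Add a length-d vector to every row of an n x d matrix (column-major fill).
addRowVec <- function(M, v) M + rep(v, each = nrow(M))

# Numerically stable row-wise softmax (max.col avoids an apply()).
softmaxRows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

softmaxVec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# log(sum(exp(z))) without overflow.
logSumExp <- function(z) {
  m <- max(z)
  m + log(sum(exp(z - m)))
}

stopIfNotFinite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}
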