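#' Add clipped Gaussian noise to a pattern matrix
#'
#' Adds seeded i.i.d. Gaussian noise of standard deviation `sigma` to every
#' entry. Negative results are clipped to 0 by default so the output remains
#' a valid non-negative pattern matrix; set `clip = FALSE` to keep the raw
#' (possibly signed) matrix.
#'
#' @param X a [PatternMatrix] or matrix.
#' @param sigma noise standard deviation (`>= 0`).
#' @param seed integer seed; the same seed reproduces the same noise.
#' @param clip clip negatives to 0 (default `TRUE`).
#' @return Object of the same type as `X` (a plain matrix when
#'   `clip = FALSE`, since signed values cannot live in a [PatternMatrix]).
#' @export
addGaussianNoise <- function(X, sigma, seed = 1L, clip = TRUE) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  isPM <- is(X, "PatternMatrix")
  v <- if (isPM) patterns(X) else X
  if (sigma > 0) {
    noise <- withr::with_seed(seed, matrix(stats::rnorm(length(v), sd = sigma),
                                           nrow(v), ncol(v)))
    v <- v + noise
  }
  if (clip) {
    v <- pmax(v, 0)
    if (isPM) {
      return(PatternMatrix(v, imageShape(X), channelMode(X)))
    }
    return(v)
  }
  v
}

#' Randomly drop pixels from a pattern
#'
#' Keeps the values of a chosen pixel subset and sets the rest exactly to
#' zero. The kept set is either given explicitly (`keepIndices`, 1-based) or
#' drawn uniformly without replacement (`keepCount` pixels, seeded).
#'
#' @param x numeric pattern vector.
#' @param keepCount number of pixels to keep (`0 <= keepCount <= length(x)`).
#' @param keepIndices explicit 1-based indices to keep (overrides
#'   `keepCount`).
#' @param seed integer seed for the random subset.
#' @return Pattern vector with dropped entries set to 0. The kept index set
#'   is attached as attribute `kept`.
#' @export
pixelDropout <- function(x, keepCount = NULL, keepIndices = NULL, seed = 1L) {
  M <- length(x)
  if (is.null(keepIndices)) {
    if (is.null(keepCount)) stop("supply keepCount or keepIndices", call. = FALSE)
    if (keepCount < 0 || keepCount > M) {
      stop("keepCount must be in [0, length(x)]", call. = FALSE)
    }
    keepIndices <- withr::with_seed(seed, sample.int(M, keepCount))
  } else {
    keepIndices <- as.integer(keepIndices)
    if (length(keepIndices) > 0 &&
        (min(keepIndices) < 1L || max(keepIndices) > M)) {
      stop("keepIndices out of range", call. = FALSE)
    }
  }
  out <- numeric(M)
  out[keepIndices] <- x[keepIndices]
  structure(out, kept = sort(keepIndices))
}

#' Occlude a rectangular image region
#'
#' Sets pixels inside a half-open rectangle to zero. The rectangle is given
#' in the package's coordinate convention: 0-based row/column indices with
#' origin at the top-left, covering rows `[row0, row1)` and columns
#' `[col0, col1)`.
#'
#' @param x numeric pattern vector (row-major vectorized image).
#' @param shape integer `(height, width)`.
#' @param rect integer vector `(row0, col0, row1, col1)`, half-open.
#' @return Pattern vector with the occluded region zeroed.
#' @examples
#' x <- rep(1, 16)
#' sum(occlude(x, c(4, 4), c(0, 0, 2, 4)) == 0) # top half: 8 pixels
#' @export
occlude <- function(x, shape, rect) {
  shape <- as.integer(shape)
  if (length(x) != prod(shape)) {
    stop("pattern length does not match image shape", call. = FALSE)
  }
  rect <- as.integer(rect)
  if (length(rect) != 4L) stop("rect must be (row0, col0, row1, col1)",
                               call. = FALSE)
  r0 <- rect[1L]; c0 <- rect[2L]; r1 <- rect[3L]; c1 <- rect[4L]
  if (r0 < 0L || c0 < 0L || r1 > shape[1L] || c1 > shape[2L] ||
      r0 > r1 || c0 > c1) {
    stop("rect outside image bounds", call. = FALSE)
  }
  if (r0 == r1 || c0 == c1) return(x)
  img <- vecToImage(x, shape)
  img[(r0 + 1L):r1, (c0 + 1L):c1] <- 0
  imageToVec(img)
}

#' Monte-Carlo robustness of identification under pixel dropout
#'
#' For each retained-pixel count and repetition, draws a training pattern and
#' a random pixel subset (without replacement), applies [pixelDropout()],
#' encodes the corrupted pattern with [sparseEncode()], and scores the code
#' against the training library: the specificity Z at the true index and
#' whether the pattern is correctly identified. Per-rep solver problems are
#' recorded, not fatal. Fully seeded and reproducible.
#'
#' @param X training [PatternMatrix].
#' @param Phi learned [Dictionary].
#' @param ATraining training code library ([CodeMatrix]); computed by
#'   [encodeMatrix()] when `NULL`.
#' @param pixelCounts vector of retained-pixel counts, each in `[2, M]`.
#' @param reps repetitions per count (default 100).
#' @param config an [encodeConfig()] for the per-trial encoding.
#' @param seed integer master seed.
#' @return List with `trials` (data.frame: `pixelCount`, `rep`,
#'   `patternIndex`, `zTrue`, `identified`, `failed`) and `aggregate`
#'   (data.frame: `pixelCount`, `meanZ`, `sdZ`, `idRate`, `nOk`).
#' @export
monteCarloSpecificity <- function(X, Phi, ATraining = NULL, pixelCounts,
                                  reps = 100L, config = NULL, seed = 1L) {
  stopifnot(is(X, "PatternMatrix"))
  M <- nrow(patterns(X))
  if (any(pixelCounts < 2) || any(pixelCounts > M)) {
    stop("pixelCounts must lie in [2, M]", call. = FALSE)
  }
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  if (is.null(ATraining)) ATraining <- encodeMatrix(X, Phi, config = config)
  Atr <- codes(ATraining)
  Xv <- patterns(X)
  PhiM <- if (is(Phi, "Dictionary")) atoms(Phi) else Phi
  gram <- dictGram(PhiM)
  if (is.null(config)) config <- encodeConfig()

  nTrials <- length(pixelCounts) * reps
  draws <- withr::with_seed(seed, {
    list(pattern = sample.int(ncol(Xv), nTrials, replace = TRUE),
         subsetSeeds = sample.int(.Machine$integer.max - 1L, nTrials))
  })

  trials <- data.frame(
    pixelCount = rep(pixelCounts, each = reps),
    rep = rep(seq_len(reps), times = length(pixelCounts)),
    patternIndex = draws$pattern,
    zTrue = NA_real_, identified = NA, failed = FALSE
  )
  for (t in seq_len(nTrials)) {
    j <- trials$patternIndex[t]
    cnt <- trials$pixelCount[t]
    xCorrupt <- pixelDropout(Xv[, j], keepCount = cnt,
                             seed = draws$subsetSeeds[t])
    out <- tryCatch({
      enc <- sparseEncodeCore(as.vector(xCorrupt), PhiM, config$epsilon,
                              config$maxIter, config$tol, gram = gram)
      spec <- specificityZscore(enc$a, Atr, trueIndex = j)
      list(z = spec$z[j], id = spec$argmax == j)
    }, error = function(e) NULL)
    if (is.null(out)) {
      trials$failed[t] <- TRUE
    } else {
      trials$zTrue[t] <- out$z
      trials$identified[t] <- out$id
    }
  }
  ok <- !trials$failed
  agg <- do.call(rbind, lapply(pixelCounts, function(cnt) {
    sel <- ok & trials$pixelCount == cnt
    data.frame(
      pixelCount = cnt,
      meanZ = mean(trials$zTrue[sel]),
      sdZ = stats::sd(trials$zTrue[sel]),
      idRate = mean(trials$identified[sel]),
      nOk = sum(sel)
    )
  }))
  list(trials = trials, aggregate = agg)
}
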