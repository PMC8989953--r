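#' Split signed patches into On/Off channels
#'
#' Rectifies mean-centered (signed) patches into a non-negative On channel
#' (positive part) and Off channel (positive part of the negation), stacked
#' On-then-Off along the rows. For every pixel at most one channel is
#' non-zero, and `On - Off` recovers the original signed patch exactly, so
#' the construction is information-preserving. This models the mammalian
#' On-/Off-center pathways feeding the dictionary learner, which requires
#' non-negative inputs.
#'
#' @param patches numeric `M x N` matrix of signed, per-patch mean-centered
#'   patches (columns are row-major vectorized images).
#' @param shape integer `(height, width)` with `height * width = M`.
#' @return A [PatternMatrix] in `"onoff"` mode with `2M` rows.
#' @export
makeOnOff <- function(patches, shape) {
  if (!all(is.finite(patches))) {
    stop("patches contain non-finite values", call. = FALSE)
  }
  if (is.vector(patches)) patches <- matrix(patches, ncol = 1L)
  if (nrow(patches) != prod(shape)) {
    stop("patch length does not match image shape", call. = FALSE)
  }
  on <- pmax(patches, 0)
  off <- pmax(-patches, 0)
  PatternMatrix(rbind(on, off), imageShape = shape, channelMode = "onoff")
}

#' Extract projective fields from an On/Off dictionary
#'
#' Each atom of an On/Off-trained dictionary is turned into a signed
#' projective field by superposing its On-channel half with the negative of
#' its Off-channel half and reshaping to the image.
#'
#' @param Phi a [Dictionary] in `"onoff"` mode (or a matrix with an even row
#'   count plus `shape`).
#' @param shape required when `Phi` is a plain matrix.
#' @return List of `height x width` signed matrices, one per atom.
#' @export
projectiveFields <- function(Phi, shape = NULL) {
  if (is(Phi, "Dictionary")) {
    if (channelMode(Phi) != "onoff") {
      stop("dictionary is not in onoff mode", call. = FALSE)
    }
    shape <- imageShape(Phi)
    Phi <- atoms(Phi)
  }
  if (nrow(Phi) %% 2L != 0L) {
    stop("onoff dictionary must have an even row count", call. = FALSE)
  }
  half <- nrow(Phi) / 2L
  if (is.null(shape) || prod(shape) != half) {
    stop("shape must multiply to half the row count", call. = FALSE)
  }
  lapply(seq_len(ncol(Phi)), function(k) {
    vecToImage(Phi[seq_len(half), k] - Phi[half + seq_len(half), k], shape)
  })
}

#' Classify a projective field as simple or complex
#'
#' A field is called *simple* (localized, oriented, Gabor-like) when (a) its
#' 2-D amplitude spectrum with the DC component removed concentrates at least
#' `peakTheta` of its energy in one dominant conjugate-symmetric lobe pair,
#' and (b) its spatial support is localized: the energy-weighted radius of
#' gyration, normalized by the image half-diagonal, stays below
#' `spreadBound`. Otherwise it is *complex*. The decision is invariant to
#' negating the field and to 90-degree rotations. A pure-DC field (spectrum
#' empty after DC removal) is degenerate and labelled complex.
#'
#' @param field signed `height x width` matrix (non-zero).
#' @param peakTheta spectral lobe energy fraction required for "simple"
#'   (default 0.5).
#' @param spreadBound normalized spatial spread bound (default 0.45).
#' @param lobeRadius radius (in frequency bins, torus metric) of the lobe
#'   neighborhood around the spectral peak (default 2).
#' @return List with `label` (`"simple"`/`"complex"`), `peakFraction`,
#'   `spread` (normalized radius of gyration), and `degenerate`.
#' @export
classifyReceptiveField <- function(field, peakTheta = 0.5,
                                   spreadBound = 0.45, lobeRadius = 2) {
  if (!is.matrix(field) || !all(is.finite(field))) {
    stop("field must be a finite numeric matrix", call. = FALSE)
  }
  energy <- field^2
  total <- sum(energy)
  if (total == 0) stop("zero field cannot be classified", call. = FALSE)

  h <- nrow(field); w <- ncol(field)

  # spatial localization: normalized radius of gyration of the energy
  rows <- row(field) - 1; cols <- col(field) - 1
  cr <- sum(rows * energy) / total
  cc <- sum(cols * energy) / total
  rg <- sqrt(sum(((rows - cr)^2 + (cols - cc)^2) * energy) / total)
  spread <- rg / (sqrt(h^2 + w^2) / 2)

  amp2 <- Mod(stats::fft(field))^2
  amp2[1L, 1L] <- 0
  specTotal <- sum(amp2)
  if (specTotal <= total * 1e-20) {
    return(list(label = "complex", peakFraction = 0, spread = spread,
                degenerate = TRUE))
  }
  pk <- arrayInd(which.max(amp2), dim(amp2))
  # torus distance to the peak and to its conjugate mirror
  fr <- (seq_len(h) - 1); fc <- (seq_len(w) - 1)
  torusDist2 <- function(p) {
    dr <- pmin(abs(fr - (p[1L] - 1L)), h - abs(fr - (p[1L] - 1L)))
    dc <- pmin(abs(fc - (p[2L] - 1L)), w - abs(fc - (p[2L] - 1L)))
    outer(dr^2, dc^2, "+")
  }
  conj <- c((h - (pk[1L] - 1L)) %% h + 1L, (w - (pk[2L] - 1L)) %% w + 1L)
  mask <- torusDist2(pk) <= lobeRadius^2 | torusDist2(conj) <= lobeRadius^2
  peakFraction <- sum(amp2[mask]) / specTotal

  simple <- peakFraction >= peakTheta && spread <= spreadBound
  list(label = if (simple) "simple" else "complex",
       peakFraction = peakFraction, spread = spread, degenerate = FALSE)
}

#' Fraction of simple projective fields versus training-set size
#'
#' Trains one dictionary per training size on synthetic On/Off natural-image
#' patches, extracts projective fields, classifies each, and tabulates the
#' fraction labelled simple together with the mean normalized spatial spread.
#' Seeded end to end.
#'
#' @param trainingSizes increasing vector of patch counts.
#' @param K representation dimension (fixed across sizes).
#' @param patchShape patch `(height, width)` (default `c(16, 16)`).
#' @param beta spectral exponent of the patch generator (default 2).
#' @param seed master seed.
#' @param learnArgs list of extra arguments to [learnConfig()].
#' @param patchArgs list of extra arguments to [generatePatches()].
#' @param classifyArgs list of extra arguments to
#'   [classifyReceptiveField()].
#' @return data.frame with `nPatches`, `fractionSimple`, `meanSpread`,
#'   `nAtoms`.
#' @export
simpleFractionCurve <- function(trainingSizes, K, patchShape = c(16L, 16L),
                                beta = 2, seed = 1L, learnArgs = list(),
                                patchArgs = list(), classifyArgs = list()) {
  if (any(diff(trainingSizes) <= 0)) {
    stop("trainingSizes must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(seq_along(trainingSizes), function(i) {
    n <- trainingSizes[i]
    patches <- do.call(generatePatches, c(
      list(n = n, shape = patchShape, beta = beta, seed = seed + i),
      patchArgs
    ))
    X <- makeOnOff(patches, patchShape)
    cfg <- do.call(learnConfig, c(list(K = K, seed = seed + 1000L + i),
                                  learnArgs))
    fit <- learnDictionary(X, cfg)
    pfs <- projectiveFields(dictionary(fit))
    cls <- lapply(pfs, function(f) {
      do.call(classifyReceptiveField, c(list(field = f), classifyArgs))
    })
    labels <- vapply(cls, `[[`, character(1L), "label")
    spreads <- vapply(cls, `[[`, numeric(1L), "spread")
    data.frame(nPatches = n,
               fractionSimple = mean(labels == "simple"),
               meanSpread = mean(spreads),
               nAtoms = length(pfs))
  })
  do.call(rbind, rows)
}
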