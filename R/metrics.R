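#' Redundancy of a binary code
#'
#' Treats `N` objects as equiprobable, so the object entropy is
#' `H(O) = log2(N)` bits, computes the summed binary-channel capacity of the
#' coding units from their activation probabilities `p_i` (row means),
#' \deqn{C = \sum_i p_i \log_2(1/p_i) + (1 - p_i)\log_2(1/(1-p_i)),}
#' and reports the redundancy `R = 1 - H(O)/C`. Callers binarize continuous
#' codes first (see [binarizeCodes()]).
#'
#' @param binaryActivity `L x N` matrix with entries in \{0, 1\} (units x
#'   objects), or a [CodeMatrix] (binarized with its own threshold).
#' @param nObjects number of objects; defaults to `ncol(binaryActivity)`.
#' @return List with elements `p` (per-unit activation probabilities),
#'   `capacity` (bits), `entropyObjects` (bits), and `redundancy`.
#' @examples
#' B <- diag(4) # four one-hot units for four objects
#' redundancy(B)$redundancy
#' @export
redundancy <- function(binaryActivity, nObjects = NULL) {
  if (is(binaryActivity, "CodeMatrix")) {
    binaryActivity <- binarizeCodes(binaryActivity)
  }
  if (!all(binaryActivity %in% c(0, 1))) {
    stop("binaryActivity must contain only 0/1 entries", call. = FALSE)
  }
  if (is.null(nObjects)) nObjects <- ncol(binaryActivity)
  p <- rowMeans(binaryActivity)
  capacity <- sum(binaryEntropy(p))
  if (capacity == 0) {
    stop("all units are constant: capacity is 0 and redundancy undefined",
         call. = FALSE)
  }
  entropyObjects <- log2(nObjects)
  list(p = p, capacity = capacity, entropyObjects = entropyObjects,
       redundancy = 1 - entropyObjects / capacity)
}

#' Binarize a code matrix with its Heaviside threshold
#'
#' @param A a [CodeMatrix] or numeric matrix.
#' @param threshold override; defaults to the object's threshold, or
#'   `1e-3 * max(A)` for plain matrices.
#' @return 0/1 matrix of the same shape.
#' @export
binarizeCodes <- function(A, threshold = NULL) {
  if (is(A, "CodeMatrix")) {
    if (is.null(threshold)) threshold <- binarizationThreshold(A)
    A <- codes(A)
  }
  if (is.null(threshold)) threshold <- defaultThreshold(A)
  binarize(A, threshold)
}

#' Per-pixel Kullback-Leibler divergence between dictionary and patterns
#'
#' Quantifies how much the pixel-occupancy statistics of the dictionary
#' elements diverge from those of the encoded patterns. Both matrices are
#' Heaviside-binarized; for pixel `i`, `P_i = n/K` is the fraction of atoms
#' in which it is active and `Q_i = m/N` the fraction of patterns, and
#' \deqn{D_{KL}(x_i) = P_i\log_2\frac{P_i}{Q_i} + (1-P_i)\log_2\frac{1-P_i}{1-Q_i}}
#' (bits, `0 log 0 := 0`). Support mismatches (`P_i > 0` with `Q_i = 0`, or
#' `P_i < 1` with `Q_i = 1`) yield an infinite divergence, returned as `Inf`
#' with the `infinite` flag set rather than as an error.
#'
#' @param Phi a [Dictionary] or matrix.
#' @param X a [PatternMatrix] or matrix with the same number of rows.
#' @param threshold Heaviside threshold; default `1e-3 * max(.)` applied to
#'   each matrix separately.
#' @return data.frame with columns `pixel` (1-based row index), `P`, `Q`,
#'   `dkl`, `infinite`.
#' @export
klDivergencePixels <- function(Phi, X, threshold = NULL) {
  if (is(Phi, "Dictionary")) Phi <- atoms(Phi)
  if (is(X, "PatternMatrix")) X <- patterns(X)
  if (nrow(Phi) != nrow(X)) {
    stop("dictionary and pattern matrix row counts differ", call. = FALSE)
  }
  thP <- if (is.null(threshold)) defaultThreshold(Phi) else threshold
  thX <- if (is.null(threshold)) defaultThreshold(X) else threshold
  P <- rowMeans(binarize(Phi, thP))
  Q <- rowMeans(binarize(X, thX))
  term <- function(p, q) {
    out <- numeric(length(p))
    pos <- p > 0
    out[pos & q == 0] <- Inf
    ok <- pos & q > 0
    out[ok] <- p[ok] * log2(p[ok] / q[ok])
    out
  }
  dkl <- term(P, Q) + term(1 - P, 1 - Q)
  data.frame(pixel = seq_along(P), P = P, Q = Q, dkl = dkl,
             infinite = !is.finite(dkl))
}

#' Z-scored specificity of a test representation
#'
#' Computes the cosine similarity of a test code against every column of a
#' training code library and standardizes the similarities with the sample
#' (n-1) standard deviation. A high Z at the true object's index indicates a
#' specific, identity-preserving representation.
#'
#' @param aTest numeric code vector (non-zero).
#' @param ATraining a [CodeMatrix] or `K x N` matrix with non-zero columns.
#' @param trueIndex optional 1-based index of the true object.
#' @return List with `cosine`, `z`, `argmax` (lowest index on ties), and
#'   `correct` (`NA` when `trueIndex` is missing).
#' @export
specificityZscore <- function(aTest, ATraining, trueIndex = NULL) {
  if (is(ATraining, "CodeMatrix")) ATraining <- codes(ATraining)
  cs <- cosineSimCols(aTest, ATraining)
  s <- stats::sd(cs)
  if (!is.finite(s) || s == 0) {
    stop("cosine similarities are constant; Z-scores undefined", call. = FALSE)
  }
  z <- (cs - mean(cs)) / s
  am <- which.max(z)
  list(cosine = cs, z = z, argmax = am,
       correct = if (is.null(trueIndex)) NA else am == trueIndex)
}

#' Identify a pattern from its representation
#'
#' Returns the index of the training representation at minimum cosine
#' distance (maximum cosine similarity) from the test code; ties are broken
#' by the lowest index.
#'
#' @inheritParams specificityZscore
#' @return Integer index into the training library.
#' @export
identifyPattern <- function(aTest, ATraining) {
  if (is(ATraining, "CodeMatrix")) ATraining <- codes(ATraining)
  which.max(cosineSimCols(aTest, ATraining))
}

#' Per-column l0 sparsity of a code matrix
#'
#' Fraction of entries per column strictly above the Heaviside binarization
#' threshold, i.e. the fraction of active representation units per pattern.
#'
#' @param A a [CodeMatrix] or matrix.
#' @param threshold override for plain matrices.
#' @return Numeric vector in `[0, 1]`, one entry per pattern.
#' @export
codeSparsity <- function(A, threshold = NULL) {
  B <- binarizeCodes(A, threshold)
  colMeans(B)
}

#' Pairwise correlation of representation units
#'
#' Pearson correlation of unit activations across patterns. Constant units
#' (zero variance) are excluded from the summary; near-identity correlation
#' structure indicates decorrelated coding.
#'
#' @param A a [CodeMatrix] or `K x N` matrix with `N >= 2`.
#' @return List with `correlation` (K x K, `NA` rows for constant units),
#'   `meanAbsOffDiagonal`, and `nConstantUnits`.
#' @export
unitCorrelation <- function(A) {
  if (is(A, "CodeMatrix")) A <- codes(A)
  if (ncol(A) < 2L) {
    stop("need at least two patterns to correlate units", call. = FALSE)
  }
  sds <- apply(A, 1L, stats::sd)
  keep <- sds > 0
  C <- matrix(NA_real_, nrow(A), nrow(A))
  if (sum(keep) >= 2L) {
    Ck <- stats::cor(t(A[keep, , drop = FALSE]))
    C[keep, keep] <- Ck
    off <- Ck[upper.tri(Ck)]
    summary <- mean(abs(off))
  } else {
    summary <- NA_real_
  }
  list(correlation = C, meanAbsOffDiagonal = summary,
       nConstantUnits = sum(!keep))
}

#' Informativeness of dictionary elements about object identity
#'
#' Plug-in mutual information (bits) between the Heaviside-binarized
#' activation of each representation unit across the encoded training set and
#' object identity under a uniform object prior. Because the binarized
#' activation is a deterministic function of the object, the information of
#' unit `j` reduces to the binary entropy of its activation frequency
#' `p_j = n_j / N`; a unit active for exactly one of `N` objects carries
#' `(1/N)log2(N) + ((N-1)/N)log2(N/(N-1))` bits, and a unit active for all
#' (or none) carries 0. Also returns the vector normalized to the maximum
#' observed information.
#'
#' @param Phi a [Dictionary] (used to encode `X` when `A` is not supplied).
#' @param X a [PatternMatrix] of the training objects.
#' @param config an [encodeConfig()] for the encoding step.
#' @param A optional precomputed training [CodeMatrix]; skips encoding.
#' @return List with `perAtomInfo` (bits), `normalizedInfo` in `[0, 1]`, and
#'   `activationFrequency`.
#' @export
atomInformation <- function(Phi, X, config = NULL, A = NULL) {
  if (is.null(A)) {
    A <- encodeMatrix(X, Phi, config = config)
  }
  B <- binarizeCodes(A)
  p <- rowMeans(B)
  info <- binaryEntropy(p)
  maxInfo <- max(info)
  normalized <- if (maxInfo > 0) info / maxInfo else info
  list(perAtomInfo = info, normalizedInfo = normalized,
       activationFrequency = p)
}

#' Fit a four-parameter logistic to a specificity curve
#'
#' Least-squares fit of
#' `z(x) = lower + (upper - lower) / (1 + exp(-slope * (x - midpoint)))`
#' to mean Z-scored specificity as a function of retained pixel count, via
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#'
#' @param pixelCounts strictly increasing numeric vector (>= 4 points).
#' @param meanZ mean specificity Z at the true index for each count.
#' @return List with `lower`, `upper`, `midpoint`, `slope`, `residualNorm`,
#'   `converged`, `degenerate` (constant input flagged, no fit attempted),
#'   and `fitted`.
#' @export
fitSpecificitySigmoid <- function(pixelCounts, meanZ) {
  if (length(pixelCounts) < 4L) {
    stop("need at least 4 points to fit a 4-parameter logistic", call. = FALSE)
  }
  if (any(diff(pixelCounts) <= 0)) {
    stop("pixelCounts must be strictly increasing", call. = FALSE)
  }
  if (length(meanZ) != length(pixelCounts)) {
    stop("pixelCounts and meanZ lengths differ", call. = FALSE)
  }
  if (stats::sd(meanZ) == 0) {
    return(list(lower = meanZ[1L], upper = meanZ[1L], midpoint = NA_real_,
                slope = NA_real_, residualNorm = 0, converged = FALSE,
                degenerate = TRUE, fitted = meanZ))
  }
  df <- data.frame(x = pixelCounts, y = meanZ)
  start <- list(lower = min(meanZ), upper = max(meanZ),
                midpoint = stats::median(pixelCounts),
                slope = 4 / diff(range(pixelCounts)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ lower + (upper - lower) / (1 + exp(-slope * (x - midpoint))),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(lower = NA_real_, upper = NA_real_, midpoint = NA_real_,
                slope = NA_real_,
                residualNorm = l2norm(meanZ - mean(meanZ)),
                converged = FALSE, degenerate = FALSE, fitted = NULL))
  }
  co <- stats::coef(fit)
  list(lower = unname(co["lower"]), upper = unname(co["upper"]),
       midpoint = unname(co["midpoint"]), slope = unname(co["slope"]),
       residualNorm = l2norm(stats::residuals(fit)),
       converged = TRUE, degenerate = FALSE,
       fitted = as.vector(stats::fitted(fit)))
}
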