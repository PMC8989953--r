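#' Fit a PCA basis to a pattern set
#'
#' Principal-component baseline for the representation comparison: the top
#' `P` components of the mean-centered pattern set, computed with
#' [stats::prcomp()]. Components are orthonormal.
#'
#' @param X a [PatternMatrix] or `M x N` matrix (columns = patterns).
#' @param P number of retained components, `1 <= P <= min(M, N)`.
#' @return List of class `"PCABasis"` with `components` (`M x P`,
#'   orthonormal), `meanPattern` (length `M`), `P`, and `sdev`.
#' @export
pcaFit <- function(X, P) {
  if (is(X, "PatternMatrix")) X <- patterns(X)
  P <- as.integer(P)
  if (P < 1L || P > min(dim(X))) {
    stop("P must lie in [1, min(M, N)]", call. = FALSE)
  }
  pr <- stats::prcomp(t(X), center = TRUE, scale. = FALSE, rank. = P)
  structure(
    list(components = pr$rotation[, seq_len(P), drop = FALSE],
         meanPattern = pr$center, P = P,
         sdev = pr$sdev[seq_len(P)]),
    class = "PCABasis"
  )
}

#' Project a pattern into a PCA basis
#'
#' @param x numeric pattern vector (length `M`).
#' @param basis a `"PCABasis"` from [pcaFit()].
#' @return Numeric coefficient vector of length `P`.
#' @export
pcaEncode <- function(x, basis) {
  stopifnot(inherits(basis, "PCABasis"))
  if (length(x) != nrow(basis$components)) {
    stop("pattern length does not match basis dimension", call. = FALSE)
  }
  as.vector(crossprod(basis$components, x - basis$meanPattern))
}

#' Reconstruct a pattern from PCA coefficients
#'
#' @param coeffs numeric coefficient vector of length `P`.
#' @param basis a `"PCABasis"`.
#' @return Numeric pattern vector (may contain negative values; PCA carries
#'   no non-negativity constraint).
#' @export
pcaReconstruct <- function(coeffs, basis) {
  stopifnot(inherits(basis, "PCABasis"))
  if (length(coeffs) != basis$P) {
    stop("coefficient length does not match basis size", call. = FALSE)
  }
  as.vector(basis$components %*% coeffs + basis$meanPattern)
}
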