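# Internal helpers shared across modules.

# Image vectorization convention: row-major, origin top-left, 0-based pixel
# indices where indices are exposed. Rectangles are half-open
# [row0, row1) x [col0, col1).

#' @noRd
vecToImage <- function(v, shape) {
  stopifnot(length(v) == prod(shape))
  matrix(v, nrow = shape[1L], ncol = shape[2L], byrow = TRUE)
}

#' @noRd
imageToVec <- function(img) {
  as.vector(t(img))
}

# 0-based (row, col) -> 1-based vector index under row-major layout
#' @noRd
pixelIndex <- function(row, col, shape) {
  row * shape[2L] + col + 1L
}

#' @noRd
checkNonNegFinite <- function(m, what = "matrix") {
  if (!all(is.finite(m))) {
    stop(what, " contains non-finite entries", call. = FALSE)
  }
  if (any(m < 0)) {
    stop(what, " contains negative entries", call. = FALSE)
  }
  invisible(TRUE)
}

# binary entropy in bits, with 0*log(0) := 0
#' @noRd
binaryEntropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  q <- p[ok]
  h[ok] <- -q * log2(q) - (1 - q) * log2(1 - q)
  h
}

#' @noRd
l2norm <- function(v) sqrt(sum(v^2))

#' @noRd
colNorms <- function(m) sqrt(colSums(m^2))

# Largest eigenvalue of a symmetric PSD matrix by power iteration; used as the
# Lipschitz constant of the quadratic data-fidelity gradient.
#' @noRd
spectralBound <- function(G, iters = 30L, seed0 = NULL) {
  k <- nrow(G)
  if (k == 1L) {
    return(abs(G[1L, 1L]))
  }
  v <- rep(1 / sqrt(k), k)
  lam <- 0
  for (i in seq_len(iters)) {
    w <- G %*% v
    nw <- l2norm(w)
    if (nw == 0) {
      return(0)
    }
    v <- as.vector(w / nw)
    lam <- nw
  }
  # small safety factor so 1/L steps stay inside the descent regime
  lam * 1.01
}

# Default Heaviside binarization threshold: strictly above
# 1e-3 * (max entry of the matrix).
#' @noRd
defaultThreshold <- function(m) {
  1e-3 * max(m, 0)
}

#' @noRd
binarize <- function(m, threshold) {
  (m > threshold) * 1L
}

#' @noRd
cosineSim <- function(x, y) {
  nx <- l2norm(x)
  ny <- l2norm(y)
  if (nx == 0 || ny == 0) {
    stop("cosine similarity undefined for zero-norm vectors", call. = FALSE)
  }
  sum(x * y) / (nx * ny)
}

# Cosine similarity of a vector against every column of a matrix.
#' @noRd
cosineSimCols <- function(x, M) {
  nx <- l2norm(x)
  nm <- colNorms(M)
  if (nx == 0) {
    stop("test vector has zero norm; cosine similarity undefined", call. = FALSE)
  }
  if (any(nm == 0)) {
    stop("training matrix has zero-norm columns; cosine similarity undefined",
         call. = FALSE)
  }
  as.vector(crossprod(M, x)) / (nx * nm)
}
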