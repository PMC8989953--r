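#' Encoding configuration
#'
#' Parameters for the non-negative l1 encoder ([sparseEncode()]).
#'
#' @param epsilon residual l2 bound; `NULL` (default) uses
#'   `0.05 * ||x||_2` per pattern, scaling the bound with signal energy.
#' @param maxIter maximum multiplier-bisection steps.
#' @param tol relative KKT tolerance of the inner coordinate-descent solves.
#' @return A list of class `"EncodeConfig"`.
#' @export
encodeConfig <- function(epsilon = NULL, maxIter = 100L, tol = 1e-9) {
  if (!is.null(epsilon) && (!is.finite(epsilon) || epsilon < 0)) {
    stop("epsilon must be >= 0", call. = FALSE)
  }
  if (maxIter < 1L) stop("maxIter must be >= 1", call. = FALSE)
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  structure(list(epsilon = epsilon, maxIter = as.integer(maxIter), tol = tol),
            class = "EncodeConfig")
}

# Solve min_a 0.5||x - Phi a||^2 + lambda ||a||_1, a >= 0, exactly, by a
# Lawson-Hanson style active-set method on the KKT system: on the support S,
# a_S = G[S,S]^{-1} (Ptx_S - lambda); coordinates whose solution turns
# negative leave S along a feasible line step, and the off-support
# coordinate with the largest gradient excess over lambda enters. Finite and
# exact up to the linear solves; supports stay small (<= rank of Phi), so
# each step is cheap even for wide dictionaries. G = t(Phi)Phi, Ptx = t(Phi)x.
#' @noRd
nnLassoVec <- function(G, Ptx, a0, lambda, kktTol, maxSteps = NULL) {
  K <- length(Ptx)
  if (is.null(maxSteps)) maxSteps <- 10L * K + 200L
  d <- diag(G)
  scale <- max(abs(Ptx), 1)
  tolAbs <- kktTol * scale
  # entering tolerance is relative to lambda so tiny multipliers stay exact
  enterTol <- lambda * 1e-7 + 1e-13 * scale
  ridge <- 1e-12 * max(d, 1)

  a <- numeric(K)
  S <- which(a0 > tolAbs & d > 0)
  aCur <- pmax(a0[S], 0)

  solveS <- function(S) {
    GS <- G[S, S, drop = FALSE]
    diag(GS) <- diag(GS) + ridge
    as.vector(solve(GS, Ptx[S] - lambda))
  }

  for (step in seq_len(maxSteps)) {
    if (length(S) > 0L) {
      aS <- tryCatch(solveS(S), error = function(e) NULL)
      if (is.null(aS)) {
        # singular support (duplicate atoms): drop the last entrant
        S <- S[-length(S)]
        aCur <- aCur[-length(aCur)]
        next
      }
      if (any(aS <= 0)) {
        # line step from aCur towards aS up to the first zero crossing
        dir <- aS - aCur
        neg <- which(dir < 0 & aS <= 0)
        alpha <- min(aCur[neg] / (aCur[neg] - aS[neg]))
        aCur <- pmax(aCur + alpha * dir, 0)
        gone <- aCur <= tolAbs
        S <- S[!gone]
        aCur <- aCur[!gone]
        next
      }
      aCur <- aS
    }
    # off-support optimality: gradient must not exceed lambda
    grad <- Ptx - if (length(S) > 0L) as.vector(G[, S, drop = FALSE] %*% aCur) else 0
    grad[S] <- -Inf
    grad[d <= 0] <- -Inf
    jmax <- which.max(grad)
    if (grad[jmax] <= lambda + enterTol) break
    S <- c(S, jmax)
    aCur <- c(aCur, 0)
  }
  a[S] <- aCur
  a
}

#' @noRd
dictGram <- function(Phi) {
  G <- crossprod(Phi)
  list(G = G, L = spectralBound(G))
}

# Core single-vector encoder working on a plain matrix Phi with optional
# precomputed Gram structure.
#' @noRd
sparseEncodeCore <- function(x, Phi, epsilon, maxIter, tol, gram = NULL) {
  if (length(x) != nrow(Phi)) {
    stop("pattern length does not match dictionary row count", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("pattern must be finite and non-negative", call. = FALSE)
  }
  K <- ncol(Phi)
  nx <- l2norm(x)
  if (is.null(epsilon)) epsilon <- 0.05 * nx
  if (nx <= epsilon) {
    return(list(a = numeric(K), residual = nx, feasible = TRUE,
                lambda = NA_real_, epsilon = epsilon))
  }
  if (is.null(gram)) gram <- dictGram(Phi)
  G <- gram$G
  Ptx <- as.vector(crossprod(Phi, x))

  residOf <- function(a) l2norm(x - as.vector(Phi %*% a))

  # Bisection over lambda: the residual of the penalized solution is
  # non-decreasing in lambda, and the constrained optimum sits at the largest
  # lambda whose residual stays within epsilon.
  lamHi <- max(Ptx)
  if (lamHi <= 0) {
    # x has no positive correlation with any atom: only a = 0 reachable
    return(list(a = numeric(K), residual = nx, feasible = nx <= epsilon,
                lambda = NA_real_, epsilon = epsilon))
  }
  # effective-zero multiplier: keeps the l1 tie-break among least-squares
  # solutions while staying resolvable by the KKT tolerance
  lamLo <- lamHi * 1e-10
  aLo <- nnLassoVec(G, Ptx, numeric(K), lamLo, tol)
  rLo <- residOf(aLo)
  feasTol <- epsilon * (1 + 1e-6) + 1e-8 * nx
  if (rLo > feasTol) {
    # epsilon below the distance from x to the non-negative cone of Phi:
    # return the best-effort (residual-minimizing) solution
    return(list(a = aLo, residual = rLo, feasible = FALSE,
                lambda = lamLo, epsilon = epsilon))
  }
  lo <- lamLo
  hi <- lamHi
  aBest <- aLo
  lamBest <- lamLo
  a <- aLo
  for (i in seq_len(maxIter)) {
    mid <- sqrt(lo * hi)
    a <- nnLassoVec(G, Ptx, a, mid, tol)
    if (residOf(a) <= epsilon) {
      lo <- mid
      aBest <- a
      lamBest <- mid
    } else {
      hi <- mid
    }
    if (hi / lo < 1 + 1e-9) break
  }
  r <- residOf(aBest)
  list(a = aBest, residual = r, feasible = r <= feasTol, lambda = lamBest,
       epsilon = epsilon)
}

#' Encode one pattern by non-negative l1 minimization
#'
#' Computes the sparsest non-negative representation of a pattern in a learned
#' dictionary by solving the basis-pursuit style program
#' \deqn{\min_a \|a\|_1 \quad \text{s.t.}\quad \|x - \Phi a\|_2 \le \varepsilon,\ a \ge 0.}
#' Internally each Lagrangian sub-problem is solved exactly by an active-set
#' method and the multiplier is bisected so the residual meets the bound:
#' the penalized solution's residual is monotone in the multiplier, and the
#' constrained optimum is attained at the largest feasible multiplier. When
#' `epsilon` is smaller than the distance from `x` to the non-negative cone
#' of the dictionary, the residual-minimizing best-effort code is returned
#' with `feasible = FALSE` and the achieved residual.
#'
#' @param x numeric pattern vector (length `M`, non-negative), or a
#'   single-column [PatternMatrix].
#' @param Phi a [Dictionary] or `M x K` non-negative matrix.
#' @param config an [encodeConfig()]; or set `epsilon` directly.
#' @param epsilon residual bound override (default `0.05 * ||x||_2`).
#' @return Numeric code vector of length `K` with attributes `residual`
#'   (achieved l2 residual), `feasible` (logical), `epsilon`, and `lambda`
#'   (the retained multiplier). Deterministic given inputs and configuration.
#' @examples
#' Phi <- Dictionary(diag(4), imageShape = c(2, 2))
#' a <- sparseEncode(c(0.2, 0, 0.7, 0), Phi, epsilon = 0)
#' round(a, 6)
#' @export
sparseEncode <- function(x, Phi, config = NULL, epsilon = NULL) {
  if (is(x, "PatternMatrix")) {
    stopifnot(nPatterns(x) == 1L)
    x <- patterns(x)[, 1L]
  }
  if (is(Phi, "Dictionary")) Phi <- atoms(Phi)
  if (is.null(config)) config <- encodeConfig(epsilon = epsilon)
  if (!is.null(epsilon)) config$epsilon <- epsilon
  res <- sparseEncodeCore(x, Phi, config$epsilon, config$maxIter, config$tol)
  structure(res$a, residual = res$residual, feasible = res$feasible,
            epsilon = res$epsilon, lambda = res$lambda)
}

#' Encode every column of a pattern matrix
#'
#' Column-wise application of [sparseEncode()] sharing one Gram matrix; the
#' column order of `X` is preserved in the returned [CodeMatrix].
#'
#' @param X a [PatternMatrix] or non-negative matrix.
#' @param Phi a [Dictionary] or matrix.
#' @param config an [encodeConfig()].
#' @param epsilon residual bound override applied per column (default
#'   `0.05 * ||x||_2` of each column).
#' @return A [CodeMatrix] whose `metadata` holds per-column residuals,
#'   feasibility flags and epsilons.
#' @export
encodeMatrix <- function(X, Phi, config = NULL, epsilon = NULL) {
  if (is(X, "PatternMatrix")) X <- patterns(X)
  if (is(Phi, "Dictionary")) Phi <- atoms(Phi)
  if (is.null(config)) config <- encodeConfig(epsilon = epsilon)
  if (!is.null(epsilon)) config$epsilon <- epsilon
  gram <- dictGram(Phi)
  n <- ncol(X)
  A <- matrix(0, ncol(Phi), n)
  residuals <- numeric(n)
  feasible <- logical(n)
  epsUsed <- numeric(n)
  for (j in seq_len(n)) {
    res <- tryCatch(
      sparseEncodeCore(X[, j], Phi, config$epsilon, config$maxIter,
                       config$tol, gram = gram),
      error = function(e) {
        stop(sprintf("column %d: %s", j, conditionMessage(e)), call. = FALSE)
      }
    )
    A[, j] <- res$a
    residuals[j] <- res$residual
    feasible[j] <- res$feasible
    epsUsed[j] <- res$epsilon
  }
  CodeMatrix(A, metadata = list(residuals = residuals, feasible = feasible,
                                epsilon = epsUsed))
}

#' Reconstruct patterns from codes
#'
#' Linear reconstruction `Phi %*% a`: images are rebuilt by linearly
#' combining dictionary elements, and non-negativity of both factors keeps
#' the result non-negative.
#'
#' @param Phi a [Dictionary] or matrix.
#' @param a numeric code vector, [CodeMatrix], or `K x N` matrix.
#' @return Numeric vector (single code) or matrix of reconstructions.
#' @export
reconstruct <- function(Phi, a) {
  if (is(Phi, "Dictionary")) Phi <- atoms(Phi)
  if (is(a, "CodeMatrix")) a <- codes(a)
  if (is.vector(a)) {
    if (length(a) != ncol(Phi)) {
      stop("code length does not match dictionary atom count", call. = FALSE)
    }
    return(as.vector(Phi %*% a))
  }
  if (nrow(a) != ncol(Phi)) {
    stop("code rows do not match dictionary atom count", call. = FALSE)
  }
  Phi %*% a
}
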