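#' Learning configuration
#'
#' Assembles the tunable parameters of [learnDictionary()]. Defaults follow
#' the package's data-scaled conventions: the sparsity weight starts at the
#' 90th percentile of the initial correlation `|t(Phi) %*% X|` and decreases
#' linearly to `lambdaFinal` over the first 80% of outer iterations
#' (`"linear_decrease"`), with `lambdaFinal` defaulting to one tenth of the
#' median pattern column norm.
#'
#' @param K number of representation units (atoms); typically chosen larger
#'   than the input dimension so the code is dimension-expanded.
#' @param lambdaFinal final l1 penalty weight; `NULL` for the data-scaled
#'   default.
#' @param lambdaSchedule `"linear_decrease"` (default) or `"constant"`.
#' @param maxIter maximum number of outer alternating iterations.
#' @param innerIter gradient iterations per sub-problem solve.
#' @param tol relative objective-change stopping tolerance.
#' @param seed integer seed for the dictionary initialization.
#' @return A list of class `"LearnConfig"`.
#' @export
learnConfig <- function(K, lambdaFinal = NULL,
                        lambdaSchedule = c("linear_decrease", "constant"),
                        maxIter = 200L, innerIter = 40L, tol = 1e-6,
                        seed = 1L) {
  lambdaSchedule <- match.arg(lambdaSchedule)
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L) {
    stop("K must be a single integer >= 1", call. = FALSE)
  }
  if (!is.null(lambdaFinal) && (!is.finite(lambdaFinal) || lambdaFinal <= 0)) {
    stop("lambdaFinal must be > 0", call. = FALSE)
  }
  if (maxIter < 1L || innerIter < 1L) {
    stop("maxIter and innerIter must be >= 1", call. = FALSE)
  }
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  structure(
    list(K = K, lambdaFinal = lambdaFinal, lambdaSchedule = lambdaSchedule,
         maxIter = as.integer(maxIter), innerIter = as.integer(innerIter),
         tol = tol, seed = as.integer(seed)),
    class = "LearnConfig"
  )
}

# Objective 0.5 * ||X - Phi A||_F^2 + lambda * sum(A), computed from cached
# cross-products where possible.
#' @noRd
learnObjective <- function(X, Phi, A, lambda) {
  R <- X - Phi %*% A
  0.5 * sum(R * R) + lambda * sum(A)
}

# Accelerated projected gradient for
#   min_A 0.5||X - Phi A||_F^2 + lambda ||A||_1  s.t.  A >= 0
# with precomputed G = t(Phi) Phi, PtX = t(Phi) X. Momentum is restarted on
# objective increase and the best iterate is returned, so the accepted update
# never degrades the objective below the warm start.
#' @noRd
updateCodes <- function(G, PtX, A, lambda, L, nIter) {
  if (L <= 0) return(A)
  step <- 1 / L
  quadObj <- function(A) {
    # 0.5||X-PhiA||^2 + lambda sum(A) up to the constant 0.5||X||^2
    0.5 * sum(A * (G %*% A)) - sum(A * PtX) + lambda * sum(A)
  }
  best <- A
  bestObj <- quadObj(A)
  Y <- A
  tmom <- 1
  Aprev <- A
  for (it in seq_len(nIter)) {
    Anew <- Y - step * (G %*% Y - PtX)
    Anew <- pmax(Anew - step * lambda, 0)
    obj <- quadObj(Anew)
    if (obj < bestObj) {
      best <- Anew
      bestObj <- obj
    }
    if (obj > quadObj(Aprev)) {
      # adaptive restart of the momentum sequence
      tmom <- 1
      Y <- Anew
    } else {
      tnew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
      Y <- Anew + ((tmom - 1) / tnew) * (Anew - Aprev)
      tmom <- tnew
    }
    Aprev <- Anew
  }
  best
}

# Accelerated projected gradient for
#   min_Phi 0.5||X - Phi A||_F^2  s.t.  Phi >= 0, ||phi_k||_2 <= 1
# with precomputed H = A t(A), XAt = X t(A). The projection onto the
# intersection of the non-negative orthant and the unit ball is exact:
# clamp negatives, then scale columns with norm > 1 back to the sphere.
#' @noRd
updateAtoms <- function(H, XAt, Phi, L, nIter) {
  if (L <= 0) return(Phi)
  step <- 1 / L
  project <- function(P) {
    P <- pmax(P, 0)
    nn <- colNorms(P)
    over <- nn > 1
    if (any(over)) {
      P[, over] <- sweep(P[, over, drop = FALSE], 2L, nn[over], "/")
    }
    P
  }
  quadObj <- function(P) 0.5 * sum(P * (P %*% H)) - sum(P * XAt)
  best <- Phi
  bestObj <- quadObj(Phi)
  Y <- Phi
  tmom <- 1
  Pprev <- Phi
  for (it in seq_len(nIter)) {
    Pnew <- project(Y - step * (Y %*% H - XAt))
    obj <- quadObj(Pnew)
    if (obj < bestObj) {
      best <- Pnew
      bestObj <- obj
    }
    if (obj > quadObj(Pprev)) {
      tmom <- 1
      Y <- Pnew
    } else {
      tnew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
      Y <- Pnew + ((tmom - 1) / tnew) * (Pnew - Pprev)
      tmom <- tnew
    }
    Pprev <- Pnew
  }
  best
}

#' Learn a non-negative sparse dictionary
#'
#' Factorizes a non-negative pattern matrix `X` (`M x N`) into a non-negative
#' dictionary `Phi` (`M x K`) and non-negative sparse codes `A` (`K x N`) by
#' alternating minimization of
#' \deqn{\tfrac12\|X - \Phi A\|_F^2 + \lambda \|A\|_1,\quad \Phi \ge 0,\ A \ge 0,}
#' the blind-source-separation formulation of maximal dependence capturing.
#' Codes are updated by accelerated projected gradient with a non-negative
#' soft-threshold; atoms by accelerated projected gradient onto
#' \{non-negative, unit-l2-ball\} columns, then rescaled exactly to unit norm
#' (with inverse scaling of the code rows, which can only shrink the l1
#' penalty). The sparsity weight follows the configured schedule; dead atoms
#' are re-seeded from the worst-reconstructed pattern's residual. Learning
#' stops when the relative objective change falls below `tol` in the
#' constant-lambda phase, or at `maxIter`.
#'
#' @param X a [PatternMatrix] (or non-negative matrix, taken with a trivial
#'   `1 x M` image shape).
#' @param config a [learnConfig()] list; alternatively pass `K` and friends
#'   via `...` for convenience.
#' @param ... forwarded to [learnConfig()] when `config` is `NULL`.
#' @return An [MDCFit] holding the [Dictionary] (unit-l2 atoms, no all-zero
#'   columns), the training [CodeMatrix], and the objective trace.
#' @examples
#' X <- PatternMatrix(diag(4) * 0.8, imageShape = c(2, 2))
#' fit <- learnDictionary(X, K = 4, seed = 2, maxIter = 60)
#' fit
#' @export
learnDictionary <- function(X, config = NULL, ...) {
  if (is.matrix(X)) {
    X <- PatternMatrix(X, imageShape = c(1L, nrow(X)))
  }
  stopifnot(is(X, "PatternMatrix"))
  if (is.null(config)) config <- learnConfig(...)
  stopifnot(inherits(config, "LearnConfig"))

  Xv <- patterns(X)
  M <- nrow(Xv)
  N <- ncol(Xv)
  K <- config$K

  lambdaFinal <- config$lambdaFinal
  if (is.null(lambdaFinal)) {
    lambdaFinal <- 0.1 * stats::median(colNorms(Xv))
    if (lambdaFinal <= 0) lambdaFinal <- 1e-6
  }

  state <- withr::with_seed(config$seed, {
    Phi <- matrix(abs(stats::rnorm(M * K)), M, K)
    Phi <- sweep(Phi, 2L, colNorms(Phi), "/")
    A <- matrix(0, K, N)
    list(Phi = Phi, A = A, rng = .Random.seed)
  })
  Phi <- state$Phi
  A <- state$A

  # lambda schedule anchored at the initial residual correlation
  lambda0 <- as.numeric(stats::quantile(abs(crossprod(Phi, Xv)), 0.9))
  if (config$lambdaSchedule == "constant" || lambda0 <= lambdaFinal) {
    lambda0 <- lambdaFinal
  }
  rampLen <- max(1L, floor(0.8 * config$maxIter))
  lambdaAt <- function(it) {
    if (config$lambdaSchedule == "constant" || it >= rampLen) return(lambdaFinal)
    lambda0 + (lambdaFinal - lambda0) * (it - 1) / max(1L, rampLen - 1L)
  }

  trace <- vector("list", config$maxIter)
  converged <- FALSE
  prevObj <- NA_real_
  nIterDone <- 0L
  reseedRng <- config$seed + 104729L  # independent stream for reseeding

  for (it in seq_len(config$maxIter)) {
    lambda <- lambdaAt(it)
    objBefore <- learnObjective(Xv, Phi, A, lambda)

    G <- crossprod(Phi)
    LA <- spectralBound(G)
    A <- updateCodes(G, crossprod(Phi, Xv), A, lambda, LA, config$innerIter)

    H <- tcrossprod(A)
    LP <- spectralBound(H)
    Phi <- updateAtoms(H, Xv %*% t(A), Phi, LP, config$innerIter)

    # exact renormalization: scale factors are >= 1 under the ball constraint,
    # so scaling code rows down cannot increase the l1 penalty
    nn <- colNorms(Phi)
    live <- nn > 1e-12
    if (any(live)) {
      Phi[, live] <- sweep(Phi[, live, drop = FALSE], 2L, nn[live], "/")
      A[live, ] <- sweep(A[live, , drop = FALSE], 1L, nn[live], "*")
    }

    # Atoms needing a re-seed: all-zero columns always; additionally, past a
    # burn-in, unused atoms (all-zero code row) while some pattern remains
    # badly reconstructed — the standard escape from "orphaned pattern"
    # local minima. Re-seeding stops near the end so convergence can settle.
    dead <- which(!live)
    burnIn <- max(5L, floor(0.5 * rampLen))
    if (it > burnIn && it <= ceiling(0.9 * config$maxIter)) {
      unused <- which(live & apply(A, 1L, max) <= 0)
      if (length(unused) > 0L) {
        Res0 <- Xv - Phi %*% A
        colErr <- sqrt(colSums(Res0 * Res0)) / pmax(colNorms(Xv), 1e-12)
        nBad <- sum(colErr > 0.1)
        if (nBad > 0L) {
          dead <- union(dead, unused[seq_len(min(nBad, length(unused)))])
        }
      }
    }
    reseeded <- length(dead)
    if (reseeded > 0L) {
      # re-seed from the worst-reconstructed residual columns
      Res <- Xv - Phi %*% A
      worst <- order(colSums(Res * Res), decreasing = TRUE)
      jitter <- withr::with_seed(reseedRng + it, {
        matrix(abs(stats::rnorm(M * reseeded)) * 1e-3, M, reseeded)
      })
      for (d in seq_along(dead)) {
        src <- pmax(Res[, worst[(d - 1L) %% length(worst) + 1L]], 0) +
          jitter[, d]
        ns <- l2norm(src)
        Phi[, dead[d]] <- if (ns > 0) src / ns else jitter[, d] / l2norm(jitter[, d])
        A[dead[d], ] <- 0
      }
    }

    objAfter <- learnObjective(Xv, Phi, A, lambda)
    if (reseeded == 0L &&
        objAfter > objBefore * (1 + config$tol) + config$tol) {
      stop(sprintf(
        paste0("objective increased beyond tolerance at outer iteration %d ",
               "(%.8g -> %.8g); solver failure"),
        it, objBefore, objAfter
      ), call. = FALSE)
    }
    trace[[it]] <- data.frame(
      iteration = it, lambda = lambda,
      objectiveBefore = objBefore, objectiveAfter = objAfter,
      reseeded = reseeded
    )
    nIterDone <- it

    if (it > rampLen && reseeded == 0L && is.finite(prevObj)) {
      if (abs(prevObj - objAfter) < config$tol * abs(prevObj)) {
        converged <- TRUE
        trace <- trace[seq_len(it)]
        break
      }
    }
    prevObj <- objAfter
  }

  # drop any atom that never recovered
  nn <- colNorms(Phi)
  keep <- nn > 1e-12
  Phi <- Phi[, keep, drop = FALSE]
  A <- A[keep, , drop = FALSE]
  Phi <- sweep(Phi, 2L, colNorms(Phi), "/")

  dict <- Dictionary(Phi, imageShape = imageShape(X),
                     channelMode = channelMode(X))
  cm <- CodeMatrix(A, metadata = list(source = "learnDictionary"))
  new("MDCFit",
    dictionary = dict,
    codes = cm,
    objectiveTrace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
    config = c(unclass(config), list(lambdaFinalUsed = lambdaFinal,
                                     lambdaInitial = lambda0)),
    converged = converged,
    iterations = nIterDone
  )
}
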