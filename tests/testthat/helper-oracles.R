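# Independent oracles used to freeze expected values.

# Exact LP oracle for min sum(a) s.t. Phi a = x, a >= 0, by enumerating all
# basic feasible solutions (supports of size <= M). Exact for small K, M and
# entirely independent of the package's iterative solver.
bruteForceL1Oracle <- function(Phi, x, tol = 1e-9) {
  M <- nrow(Phi)
  K <- ncol(Phi)
  best <- Inf
  bestA <- NULL
  for (idx in utils::combn(K, min(M, K), simplify = FALSE)) {
    B <- Phi[, idx, drop = FALSE]
    aB <- tryCatch(qr.solve(B, x, tol = 1e-12), error = function(e) NULL)
    if (is.null(aB)) next
    if (any(aB < -tol)) next
    if (max(abs(B %*% pmax(aB, 0) - x)) > 1e-7 * max(1, max(abs(x)))) next
    val <- sum(pmax(aB, 0))
    if (val < best) {
      best <- val
      bestA <- numeric(K)
      bestA[idx] <- pmax(aB, 0)
    }
  }
  list(value = best, a = bestA)
}

# Hungarian-free optimal assignment for small K: brute-force over
# permutations, maximizing the mean cosine between matched atom pairs.
bestPermutationMeanCosine <- function(PhiLearned, PhiTrue) {
  C <- crossprod(
    sweep(PhiLearned, 2L, sqrt(colSums(PhiLearned^2)), "/"),
    sweep(PhiTrue, 2L, sqrt(colSums(PhiTrue^2)), "/")
  )
  K <- ncol(PhiTrue)
  if (K <= 7L) {
    perms <- permuteAll(seq_len(K))
    best <- -Inf
    for (p in perms) {
      v <- mean(C[cbind(p, seq_len(K))])
      if (v > best) best <- v
    }
    return(best)
  }
  # greedy assignment (upper-bounded by optimal; adequate for K > 7 checks)
  Cc <- C
  total <- 0
  for (i in seq_len(K)) {
    idx <- which(Cc == max(Cc), arr.ind = TRUE)[1L, ]
    total <- total + Cc[idx[1L], idx[2L]]
    Cc[idx[1L], ] <- -Inf
    Cc[, idx[2L]] <- -Inf
  }
  total / K
}

permuteAll <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permuteAll(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}
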