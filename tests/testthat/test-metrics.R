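test_that("redundancy reproduces closed-form channel quantities", {
  # one unit active for exactly one of two objects: a perfect one-bit code
  r <- redundancy(matrix(c(1, 0), 1, 2))
  expect_equal(r$capacity, 1)
  expect_equal(r$entropyObjects, 1)
  expect_equal(r$redundancy, 0)

  # four one-hot units over four objects, hand-evaluated
  r4 <- redundancy(diag(4))
  expect_equal(r4$capacity, 3.2451, tolerance = 1e-4)
  expect_equal(r4$redundancy, 0.3837, tolerance = 1e-4)

  # closed form for any one-hot code of N equiprobable objects
  for (N in c(3, 5, 8, 16)) {
    rN <- redundancy(diag(N))
    h <- -(1 / N) * log2(1 / N) - (1 - 1 / N) * log2(1 - 1 / N)
    expect_equal(rN$redundancy, 1 - log2(N) / (N * h), tolerance = 1e-12)
  }

  expect_error(redundancy(matrix(1, 3, 4)), "capacity")
  expect_error(redundancy(matrix(0.5, 2, 2)), "0/1")
})

test_that("per-pixel KL divergence matches the printed formula and edge cases", {
  # identical activation frequencies -> zero everywhere
  Phi <- cbind(c(1, 0, 1), c(0, 1, 1))
  X <- cbind(Phi, Phi)
  kl <- klDivergencePixels(Phi, X)
  expect_equal(kl$dkl, rep(0, 3))

  # pixel active in 5/10 atoms and 5/20 patterns: hand evaluation
  PhiB <- matrix(0, 1, 10); PhiB[1, 1:5] <- 1
  XB <- matrix(0, 1, 20); XB[1, 1:5] <- 1
  kl2 <- klDivergencePixels(PhiB, XB)
  expect_equal(kl2$dkl, 0.5 * log2(0.5 / 0.25) + 0.5 * log2(0.5 / 0.75),
               tolerance = 1e-12)
  expect_equal(kl2$dkl, 0.2075, tolerance = 1e-4)

  # support mismatch is a flagged infinity, not an error
  kl3 <- klDivergencePixels(matrix(1, 1, 4), matrix(0, 1, 6))
  expect_true(kl3$infinite)
  expect_equal(kl3$dkl, Inf)
})

test_that("KL divergence is non-negative, zero iff matched, on random grids", {
  set.seed(5)
  for (i in 1:20) {
    K <- sample(4:12, 1); N <- sample(4:12, 1); M <- 6
    Phi <- matrix(rbinom(M * K, 1, 0.5), M, K)
    X <- matrix(rbinom(M * N, 1, 0.5), M, N)
    kl <- klDivergencePixels(Phi, X)
    finite <- !kl$infinite
    expect_true(all(kl$dkl[finite] >= -1e-12))
    match <- abs(kl$P - kl$Q) < 1e-12
    expect_true(all(kl$dkl[match] == 0))
    expect_true(all(kl$dkl[finite & !match] > 0))
  }
})

test_that("specificity Z-scores use the sample-sd convention", {
  # training library engineered to produce cosines (0.9, 0.1, 0.2)
  A <- diag(3)
  spec <- specificityZscore(c(0.9, 0.1, 0.2) / sqrt(sum(c(.9, .1, .2)^2)), A)
  expect_equal(spec$cosine, c(0.9, 0.1, 0.2) / sqrt(sum(c(.9, .1, .2)^2)) ,
               tolerance = 1e-12)
  zs <- specificityZscore(c(0.9, 0.1, 0.2), diag(3))
  # hand computation with mean 0.4 and sample sd 0.43589 on the raw cosines
  cs <- c(0.9, 0.1, 0.2)
  expect_equal(zs$z, (cs - 0.4) / 0.4358899, tolerance = 1e-6)
  expect_equal(zs$z, c(1.147, -0.688, -0.459), tolerance = 1e-3)
  # standardization invariants
  expect_equal(mean(zs$z), 0, tolerance = 1e-9)
  expect_equal(sd(zs$z), 1, tolerance = 1e-9)
  expect_equal(zs$argmax, which.max(zs$cosine))
  expect_error(specificityZscore(c(0, 0, 0), diag(3)), "zero")
})

test_that("identification is argmax cosine with permutation equivariance", {
  set.seed(8)
  A <- matrix(runif(5 * 7) + 0.01, 5, 7)
  aTest <- A[, 4] + rnorm(5, sd = 0.01)
  expect_equal(identifyPattern(abs(aTest), A), 4L)
  perm <- sample(7)
  expect_equal(perm[identifyPattern(abs(aTest), A[, perm])], 4L)
  # exact self-similarity
  expect_equal(identifyPattern(A[, 2], A), 2L)
})

test_that("code sparsity counts Heaviside-active units per pattern", {
  A <- CodeMatrix(cbind(c(0, 0, 0), c(1, 2, 3), c(0, 5, 0)))
  s <- codeSparsity(A)
  expect_equal(s, c(0, 1, 1 / 3))
  # threshold excludes sub-threshold crumbs
  A2 <- CodeMatrix(cbind(c(1e-9, 1, 0)))
  expect_equal(codeSparsity(A2), 1 / 3)
})

test_that("unit correlation summarizes off-diagonal structure", {
  # one-hot codes: constant-sum columns give uniform negative off-diagonals
  A <- diag(4)
  uc <- unitCorrelation(A)
  off <- uc$correlation[upper.tri(uc$correlation)]
  expect_true(all(off <= 0))
  # duplicated unit rows correlate exactly
  A2 <- rbind(c(1, 2, 3, 1), c(1, 2, 3, 1), c(3, 1, 0, 2))
  uc2 <- unitCorrelation(A2)
  expect_equal(uc2$correlation[1, 2], 1)
  # constant rows are excluded from the summary
  A3 <- rbind(c(1, 1, 1), c(0, 1, 2), c(2, 1, 0))
  uc3 <- unitCorrelation(A3)
  expect_equal(uc3$nConstantUnits, 1L)
  expect_error(unitCorrelation(matrix(1, 2, 1)), "two patterns")
})

test_that("atom informativeness follows the binary-channel closed form", {
  # unit active for exactly 1 of N objects
  for (N in c(4, 10)) {
    B <- matrix(0, 2, N)
    B[1, 1] <- 1
    B[2, ] <- 1 # always active: zero information
    info <- atomInformation(A = CodeMatrix(B), Phi = NULL, X = NULL)
    expected <- (1 / N) * log2(N) + ((N - 1) / N) * log2(N / (N - 1))
    expect_equal(info$perAtomInfo[1], expected, tolerance = 1e-12)
    expect_equal(info$perAtomInfo[2], 0)
    expect_equal(max(info$normalizedInfo), 1)
    # bounded by the object entropy
    expect_true(all(info$perAtomInfo <= log2(N)))
  }
})

test_that("four-parameter logistic fits recover generating parameters", {
  x <- c(2, 4, 8, 16, 32, 64, 128, 256)
  truth <- list(lower = -0.2, upper = 9.5, midpoint = 30, slope = 0.12)
  y <- truth$lower + (truth$upper - truth$lower) /
    (1 + exp(-truth$slope * (x - truth$midpoint)))
  fit <- fitSpecificitySigmoid(x, y)
  expect_true(fit$converged)
  expect_equal(fit$midpoint, truth$midpoint, tolerance = 0.01 * 30)
  expect_equal(fit$upper, truth$upper, tolerance = 0.01 * 9.5)
  expect_lt(fit$residualNorm, 1e-6)
  # degenerate constant input is flagged, not fit
  flat <- fitSpecificitySigmoid(x, rep(2, 8))
  expect_true(flat$degenerate)
  expect_error(fitSpecificitySigmoid(c(1, 2, 3), c(1, 2, 3)), "4")
  expect_error(fitSpecificitySigmoid(c(1, 1, 3, 4), rep(1, 4)), "increasing")
})
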