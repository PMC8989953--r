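test_that("identity and orthonormal dictionaries encode exactly", {
  Phi <- Dictionary(diag(4), imageShape = c(2, 2))
  a <- sparseEncode(c(0.2, 0, 0.7, 0), Phi, epsilon = 0)
  expect_equal(as.vector(a), c(0.2, 0, 0.7, 0), tolerance = 1e-8)
  expect_true(attr(a, "feasible"))

  # two orthonormal one-hot atoms, x = 3 * e2
  Phi2 <- cbind(c(1, 0, 0), c(0, 1, 0))
  a2 <- sparseEncode(c(0, 3, 0), Phi2, epsilon = 0)
  expect_equal(as.vector(a2), c(0, 3), tolerance = 1e-8)
})

test_that("encoder l1 objective matches the exact LP oracle", {
  set.seed(7)
  worst <- 0
  for (i in 1:25) {
    Phi <- matrix(abs(rnorm(8 * 12)), 8, 12)
    Phi <- sweep(Phi, 2, sqrt(colSums(Phi^2)), "/")
    a0 <- numeric(12)
    a0[sample(12, 3)] <- runif(3, 0.2, 1)
    x <- as.vector(Phi %*% a0)
    a <- sparseEncode(x, Phi, epsilon = 1e-6)
    oracle <- bruteForceL1Oracle(Phi, x)
    worst <- max(worst, abs(sum(a) - oracle$value) / oracle$value)
  }
  expect_lt(worst, 1e-4)
})

test_that("infeasible epsilon is reported with the achieved residual", {
  # x far outside the cone of a single orthogonal atom
  Phi <- cbind(c(1, 0))
  a <- sparseEncode(c(0, 1), Phi, epsilon = 1e-3)
  expect_false(attr(a, "feasible"))
  expect_equal(attr(a, "residual"), 1, tolerance = 1e-6)
  expect_error(sparseEncode(c(0.5, 0.5, 0.5), Phi), "match")
  expect_error(sparseEncode(c(-0.1, 0.2), Phi), "non-negative")
})

test_that("encodeMatrix preserves column order, duplicates and metadata", {
  set.seed(3)
  Phi <- matrix(abs(rnorm(6 * 10)), 6, 10)
  Phi <- sweep(Phi, 2, sqrt(colSums(Phi^2)), "/")
  x1 <- as.vector(Phi %*% c(1, rep(0, 9)))
  x2 <- as.vector(Phi %*% c(0, 0, 2, rep(0, 7)))
  X <- cbind(x1, x2, x1)
  cm <- encodeMatrix(X, Phi, epsilon = 1e-8)
  expect_s4_class(cm, "CodeMatrix")
  A <- codes(cm)
  # duplicated input columns give identical code columns (determinism)
  expect_identical(A[, 1], A[, 3])
  # single-column call agrees with the matrix path
  a1 <- sparseEncode(x1, Phi, epsilon = 1e-8)
  expect_equal(A[, 1], as.vector(a1), tolerance = 1e-10)
  expect_length(cm@metadata$residuals, 3L)
  expect_true(all(cm@metadata$feasible))
})

test_that("1-sparse codes are recovered through construct-then-encode", {
  set.seed(11)
  Phi <- matrix(abs(rnorm(12 * 20)), 12, 20)
  Phi <- sweep(Phi, 2, sqrt(colSums(Phi^2)), "/")
  Astar <- matrix(0, 20, 6)
  for (j in 1:6) Astar[sample(20, 1), j] <- runif(1, 0.5, 2)
  X <- Phi %*% Astar
  A <- codes(encodeMatrix(X, Phi, epsilon = 1e-8))
  expect_equal(A, Astar, tolerance = 1e-5)
})

test_that("reconstruct is the linear map and respects shapes", {
  Phi <- Dictionary(matrix(runif(12), 4, 3), c(2, 2))
  expect_equal(reconstruct(Phi, c(0, 0, 0)), rep(0, 4))
  expect_equal(reconstruct(Phi, c(0, 1, 0)), atoms(Phi)[, 2])
  expect_error(reconstruct(Phi, c(1, 2)), "match")
  A <- matrix(runif(6), 3, 2)
  expect_equal(reconstruct(Phi, A), atoms(Phi) %*% A)
})

test_that("encoding round-trips uncorrupted trained symbols", {
  sf <- symbolFixture()
  Phi <- dictionary(sf$fit)
  Xv <- patterns(sf$X)
  cosines <- vapply(seq_len(8), function(j) {
    a <- sparseEncode(Xv[, j], Phi)
    rec <- reconstruct(Phi, as.vector(a))
    sum(rec * Xv[, j]) / sqrt(sum(rec^2) * sum(Xv[, j]^2))
  }, numeric(1))
  expect_true(all(cosines >= 0.95))
})
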