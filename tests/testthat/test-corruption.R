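test_that("gaussian corruption is seeded, clipped and mean-preserving", {
  X <- PatternMatrix(matrix(runif(256 * 40), 256, 40), c(16, 16))
  expect_identical(patterns(addGaussianNoise(X, 0, seed = 1)), patterns(X))
  n1 <- addGaussianNoise(X, 0.3, seed = 7)
  n2 <- addGaussianNoise(X, 0.3, seed = 7)
  expect_identical(patterns(n1), patterns(n2))
  expect_true(all(patterns(n1) >= 0))
  # pre-clipping the noise is centered: sample mean within 3 se of 0
  raw <- addGaussianNoise(X, 0.3, seed = 7, clip = FALSE)
  delta <- raw - patterns(X)
  se <- 0.3 / sqrt(length(delta))
  expect_lt(abs(mean(delta)), 3 * se)
  expect_error(addGaussianNoise(X, -1), "sigma")
})

test_that("pixel dropout keeps exactly the chosen set and zeroes the rest", {
  x <- runif(256) + 0.1
  expect_equal(as.vector(pixelDropout(x, keepCount = 256)), x)
  expect_equal(as.vector(pixelDropout(x, keepCount = 0)), rep(0, 256))
  d <- pixelDropout(x, keepCount = 60, seed = 5)
  kept <- attr(d, "kept")
  expect_length(kept, 60L)
  expect_equal(d[kept], x[kept])
  expect_true(all(d[-kept] == 0))
  # idempotent under the same keep set
  expect_equal(as.vector(pixelDropout(as.vector(d), keepIndices = kept)),
               as.vector(d))
  expect_error(pixelDropout(x, keepIndices = c(0, 5)), "range")
})

test_that("occlusion zeroes exactly the half-open rectangle", {
  x <- rep(1, 256)
  expect_equal(occlude(x, c(16, 16), c(0, 0, 0, 0)), x) # empty rect
  expect_equal(occlude(x, c(16, 16), c(0, 0, 16, 16)), rep(0, 256))
  top <- occlude(x, c(16, 16), c(0, 0, 8, 16))
  expect_equal(sum(top == 0), 128)
  # row-major convention: first 128 entries are the top half
  expect_equal(top, c(rep(0, 128), rep(1, 128)))
  # idempotent
  expect_equal(occlude(top, c(16, 16), c(0, 0, 8, 16)), top)
  expect_error(occlude(x, c(16, 16), c(0, 0, 17, 16)), "bounds")
})

test_that("monte-carlo dropout curve is seeded with full trial bookkeeping", {
  sf <- symbolFixture()
  Phi <- dictionary(sf$fit)
  counts <- c(64, 128, 256)
  mc <- monteCarloSpecificity(sf$X, Phi, ATraining = codes(sf$fit),
                              pixelCounts = counts, reps = 4, seed = 3)
  expect_equal(nrow(mc$trials), length(counts) * 4)
  expect_equal(nrow(mc$aggregate), length(counts))
  mc2 <- monteCarloSpecificity(sf$X, Phi, ATraining = codes(sf$fit),
                               pixelCounts = counts, reps = 4, seed = 3)
  expect_identical(mc$trials, mc2$trials)
  # keeping every pixel reproduces the uncorrupted-input specificity exactly
  full <- mc$trials[mc$trials$pixelCount == 256, ]
  for (k in seq_len(nrow(full))) {
    j <- full$patternIndex[k]
    a <- sparseEncode(patterns(sf$X)[, j], Phi)
    z <- specificityZscore(as.vector(a), codes(sf$fit), trueIndex = j)
    expect_equal(full$zTrue[k], z$z[j], tolerance = 1e-10)
  }
  expect_error(
    monteCarloSpecificity(sf$X, Phi, pixelCounts = c(1, 5), reps = 1),
    "pixelCounts"
  )
})
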