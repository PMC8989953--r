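test_that("symbol generator is reproducible, binary and well-separated", {
  s1 <- generateSymbols(20, seed = 3)
  s2 <- generateSymbols(20, seed = 3)
  expect_identical(patterns(s1), patterns(s2))
  v <- patterns(s1)
  expect_true(all(v %in% c(0, 1)))
  expect_equal(dim(v), c(256L, 20L))
  # pairwise Hamming distance >= 8
  d <- as.matrix(dist(t(v), method = "manhattan"))
  expect_gte(min(d[upper.tri(d)]), 8)
})

test_that("the symbol generator scales to a thousand distinct glyphs", {
  s <- generateSymbols(1000, seed = 19)
  v <- patterns(s)
  expect_equal(dim(v), c(256L, 1000L))
  expect_true(all(v %in% c(0, 1)))
  # spot-check separation on a deterministic subsample (full check is O(n^2))
  sub <- v[, seq(1, 1000, by = 25)]
  d <- as.matrix(dist(t(sub), method = "manhattan"))
  expect_gte(min(d[upper.tri(d)]), 8)
})

test_that("near-duplicate symbol pairs sit at the minimum distance", {
  s <- generateSymbols(12, seed = 5, includeSimilarPair = TRUE)
  v <- patterns(s)
  d <- colSums(abs(v[, 1:11, drop = FALSE] - v[, 12]))
  expect_equal(min(d), 8) # the near duplicate of glyph 1
  expect_equal(which.min(d), 1L)
})

test_that("face generator produces plausible bounded faces with jitter", {
  f <- generateFaces(15, seed = 2)
  v <- patterns(f)
  expect_equal(dim(v), c(625L, 15L))
  expect_true(all(v >= 0 & v <= 1))
  # jitter makes faces distinct; jitter = 0 makes them identical
  expect_gt(min(as.matrix(dist(t(v)))[upper.tri(diag(15))]), 0)
  f0 <- generateFaces(3, seed = 2, jitter = 0)
  v0 <- patterns(f0)
  expect_equal(v0[, 1], v0[, 2])
})

test_that("face alterations are local or exact half-plane zeroings", {
  f <- generateFaces(2, seed = 9)
  x <- patterns(f)[, 1]
  shape <- c(25, 25)
  xl <- applyAlteration(x, shape, "occlude_left")
  img <- mdcoding:::vecToImage(xl, shape)
  expect_true(all(img[, 1:12] == 0))
  expect_equal(img[, 13:25], mdcoding:::vecToImage(x, shape)[, 13:25])
  # sunglasses change only the eye band rows
  xs <- applyAlteration(x, shape, "sunglasses")
  di <- mdcoding:::vecToImage(xs, shape) - mdcoding:::vecToImage(x, shape)
  changed <- which(rowSums(abs(di)) > 0)
  expect_true(all(changed >= 8 & changed <= 12))
  # mustache and sunglasses commute into "both"
  expect_equal(applyAlteration(applyAlteration(x, shape, "sunglasses"),
                               shape, "mustache"),
               applyAlteration(x, shape, "both"))
  expect_error(applyAlteration(x, shape, "hat"), "unknown")
})

test_that("patch generator hits the requested spectral slope and centering", {
  # beta = 0: white noise, flat radially averaged spectrum
  radialSpectrum <- function(P, shape) {
    h <- shape[1]; w <- shape[2]
    kr <- (seq_len(h) - 1) / h; kr <- ifelse(kr > 0.5, kr - 1, kr)
    kc <- (seq_len(w) - 1) / w; kc <- ifelse(kc > 0.5, kc - 1, kc)
    r <- sqrt(outer(kr^2, kc^2, "+"))
    pow <- matrix(0, h, w)
    for (j in seq_len(ncol(P))) {
      pow <- pow + Mod(stats::fft(mdcoding:::vecToImage(P[, j], shape)))^2
    }
    pow <- pow / ncol(P)
    bins <- cut(as.vector(r), breaks = seq(0.03, 0.5, length.out = 9))
    tapply(as.vector(pow), bins, mean)
  }
  p0 <- generatePatches(200, shape = c(16, 16), beta = 0, seed = 1,
                        edgeFraction = 0)
  expect_equal(colMeans(p0), rep(0, 200), tolerance = 1e-12)
  s0 <- radialSpectrum(p0, c(16, 16))
  expect_lt(max(abs(log(s0 / mean(s0)))), 0.35)

  # beta = 2: log-log slope of power vs frequency, per FFT bin, -2 +/- 0.2
  p2 <- generatePatches(300, shape = c(16, 16), beta = 2, seed = 2,
                        edgeFraction = 0)
  kr <- (0:15) / 16; kr <- ifelse(kr > 0.5, kr - 1, kr)
  r <- sqrt(outer(kr^2, kr^2, "+"))
  pow <- matrix(0, 16, 16)
  for (j in seq_len(ncol(p2))) {
    pow <- pow + Mod(stats::fft(mdcoding:::vecToImage(p2[, j], c(16, 16))))^2
  }
  sel <- r > 0.05 & r <= 0.5
  slope <- coef(lm(log(as.vector(pow)[sel]) ~ log(as.vector(r)[sel])))[2]
  expect_equal(unname(slope), -2, tolerance = 0.1)

  # reproducibility and error handling
  expect_identical(generatePatches(5, seed = 3), generatePatches(5, seed = 3))
  expect_error(generatePatches(5, beta = -1), "beta")
})
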