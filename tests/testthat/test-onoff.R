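test_that("On/Off rectification is complementary and information-preserving", {
  p <- c(0.5, -0.25)
  oo <- makeOnOff(matrix(p, 2, 1), c(1, 2))
  expect_equal(as.vector(patterns(oo)), c(0.5, 0, 0, 0.25))
  expect_equal(channelMode(oo), "onoff")

  set.seed(4)
  patches <- generatePatches(10, shape = c(8, 8), seed = 4)
  oo2 <- makeOnOff(patches, c(8, 8))
  v <- patterns(oo2)
  on <- v[1:64, ]; off <- v[65:128, ]
  expect_true(all(on * off == 0)) # per-pixel complementarity
  expect_equal(on - off, patches) # exact round trip
  # zero patch maps to zero channels
  oo3 <- makeOnOff(matrix(0, 4, 1), c(2, 2))
  expect_true(all(patterns(oo3) == 0))
  expect_error(makeOnOff(matrix(NA_real_, 4, 1), c(2, 2)), "finite")
})

test_that("projective fields invert the On/Off construction exactly", {
  g <- makeGabor(c(16, 16), wavelength = 4, sigma = 2, theta = pi / 3)
  g <- g - mean(g)
  oo <- makeOnOff(matrix(mdcoding:::imageToVec(g), ncol = 1), c(16, 16))
  d <- Dictionary(patterns(oo), c(16, 16), "onoff")
  pf <- projectiveFields(d)
  expect_length(pf, 1L)
  expect_equal(pf[[1]], g, tolerance = 1e-12)
  # zero Off half: field equals the On half
  atom <- c(runif(4), rep(0, 4))
  d2 <- Dictionary(matrix(atom, ncol = 1), c(2, 2), "onoff")
  expect_equal(mdcoding:::imageToVec(projectiveFields(d2)[[1]]), atom[1:4])
  expect_error(projectiveFields(matrix(1, 5, 1), shape = c(1, 2)), "even")
})

test_that("parametric Gabors classify simple; spread fields classify complex", {
  for (wl in c(3, 4, 5)) {
    for (th in c(0, pi / 4, pi / 2, 2)) {
      g <- makeGabor(c(16, 16), wavelength = wl, sigma = 2, theta = th)
      cls <- classifyReceptiveField(g - mean(g))
      expect_equal(cls$label, "simple",
                   label = sprintf("gabor wl=%g theta=%.2f", wl, th))
    }
  }
  # uniform random positive field: energy spread in space and frequency
  set.seed(9)
  for (i in 1:5) {
    noise <- matrix(runif(256), 16, 16)
    expect_equal(classifyReceptiveField(noise)$label, "complex")
  }
  # pure DC field is degenerate
  dc <- classifyReceptiveField(matrix(1, 16, 16))
  expect_equal(dc$label, "complex")
  expect_true(dc$degenerate)
  expect_error(classifyReceptiveField(matrix(0, 8, 8)), "zero")
})

test_that("classification is invariant to negation and 90-degree rotation", {
  g <- makeGabor(c(16, 16), wavelength = 4, sigma = 2, theta = pi / 5)
  g <- g - mean(g)
  base <- classifyReceptiveField(g)
  neg <- classifyReceptiveField(-g)
  rot <- classifyReceptiveField(t(g[nrow(g):1, ]))
  expect_equal(neg$label, base$label)
  expect_equal(neg$peakFraction, base$peakFraction, tolerance = 1e-12)
  expect_equal(rot$label, base$label)
})

test_that("simple-fraction curve is tabulated and reproducible", {
  sizes <- c(60, 120)
  args <- list(maxIter = 40, innerIter = 20)
  t1 <- simpleFractionCurve(sizes, K = 24, patchShape = c(8, 8), seed = 2,
                            learnArgs = args)
  expect_equal(t1$nPatches, sizes)
  expect_true(all(t1$fractionSimple >= 0 & t1$fractionSimple <= 1))
  t2 <- simpleFractionCurve(sizes, K = 24, patchShape = c(8, 8), seed = 2,
                            learnArgs = args)
  expect_identical(t1, t2)
  expect_error(simpleFractionCurve(c(10, 10), K = 4), "increasing")
})
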