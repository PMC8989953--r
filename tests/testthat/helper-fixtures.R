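# Shared fixtures, built in code. Heavier shared objects are created lazily
# and cached for the session so several test files can reuse one training
# run.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# planted sparse factorization model: X = Phi* A* + |noise|
makePlantedModel <- function(M, K, N, sparsity, sigma, seed) {
  withr::with_seed(seed, {
    Phi <- matrix(abs(stats::rnorm(M * K)), M, K)
    Phi <- sweep(Phi, 2L, sqrt(colSums(Phi^2)), "/")
    A <- matrix(0, K, N)
    for (j in seq_len(N)) {
      A[sample.int(K, sparsity), j] <- stats::runif(sparsity, 0.5, 1.5)
    }
    X <- Phi %*% A + abs(matrix(stats::rnorm(M * N, sd = sigma), M, N))
    list(Phi = Phi, A = A, X = X)
  })
}

# small trained symbol model shared across metric / corruption tests
symbolFixture <- function() {
  fixture("symbolFit", function() {
    X <- generateSymbols(40, seed = 11)
    fit <- learnDictionary(X, K = 80, seed = 5, maxIter = 120, innerIter = 30)
    list(X = X, fit = fit)
  })
}

# a synthetic Gabor patch (signed), 0-based pixel grid
makeGabor <- function(shape, wavelength, sigma, theta, phase = 0,
                      center = NULL) {
  h <- shape[1L]; w <- shape[2L]
  if (is.null(center)) center <- c((h - 1) / 2, (w - 1) / 2)
  r <- matrix(rep(0:(h - 1), w), h, w) - center[1L]
  c <- matrix(rep(0:(w - 1), each = h), h, w) - center[2L]
  xr <- c * cos(theta) + r * sin(theta)
  yr <- -c * sin(theta) + r * cos(theta)
  exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / wavelength + phase)
}
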