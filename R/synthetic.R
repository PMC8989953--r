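# Seeded generators of surrogate datasets: structured binary glyphs,
# parametric face-like images, and natural-image-like patches. They match the
# format, scale and qualitative statistics of the corresponding experimental
# datasets (binary structured symbols, frontal face layouts, ~1/f^2 spatial
# spectra with oriented structure) without claiming distributional
# equivalence to any particular image collection.

# ---- raster primitives (0-based coordinates, origin top-left) -------------

#' @noRd
rasterSegment <- function(img, r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) * 2L + 1L
  t <- seq(0, 1, length.out = n)
  rr <- round(r0 + t * (r1 - r0)) + 1L
  cc <- round(c0 + t * (c1 - c0)) + 1L
  ok <- rr >= 1L & rr <= nrow(img) & cc >= 1L & cc <= ncol(img)
  img[cbind(rr[ok], cc[ok])] <- 1L
  img
}

#' @noRd
rasterArc <- function(img, cr, cc, ry, rx, th0, th1) {
  n <- max(16L, ceiling(4 * (ry + rx)))
  th <- seq(th0, th1, length.out = n)
  rr <- round(cr + ry * sin(th)) + 1L
  ccs <- round(cc + rx * cos(th)) + 1L
  ok <- rr >= 1L & rr <= nrow(img) & ccs >= 1L & ccs <= ncol(img)
  img[cbind(rr[ok], ccs[ok])] <- 1L
  img
}

#' @noRd
randomGlyph <- function(shape, strokeRange) {
  h <- shape[1L]; w <- shape[2L]
  img <- matrix(0L, h, w)
  nStrokes <- sample(seq(strokeRange[1L], strokeRange[2L]), 1L)
  for (s in seq_len(nStrokes)) {
    type <- sample(c("segment", "arc", "ellipse"), 1L,
                   prob = c(0.5, 0.25, 0.25))
    if (type == "segment") {
      img <- rasterSegment(img,
        sample(0:(h - 1L), 1L), sample(0:(w - 1L), 1L),
        sample(0:(h - 1L), 1L), sample(0:(w - 1L), 1L))
    } else {
      cr <- stats::runif(1, h * 0.2, h * 0.8)
      cc <- stats::runif(1, w * 0.2, w * 0.8)
      ry <- stats::runif(1, 1.5, h * 0.4)
      rx <- stats::runif(1, 1.5, w * 0.4)
      if (type == "ellipse") {
        img <- rasterArc(img, cr, cc, ry, rx, 0, 2 * pi)
      } else {
        th0 <- stats::runif(1, 0, 2 * pi)
        img <- rasterArc(img, cr, cc, ry, rx, th0,
                         th0 + stats::runif(1, pi / 2, 1.5 * pi))
      }
    }
  }
  img
}

#' Generate unique structured binary glyphs
#'
#' Procedurally draws `n` binary symbol images composed of random strokes,
#' arcs and ellipses, enforcing a minimum pairwise Hamming distance so every
#' glyph is a distinct object. With `includeSimilarPair = TRUE` the last
#' glyph is replaced by a near-duplicate of the first, sitting exactly at
#' the minimum allowed distance, to probe discrimination of highly similar
#' objects.
#'
#' @param n number of glyphs.
#' @param shape image `(height, width)` (default `c(16, 16)`).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param strokeRange inclusive range of strokes per glyph (default 2-5).
#' @param dMin minimum pairwise Hamming distance in pixels (default 8).
#' @param includeSimilarPair add a near-duplicate pair (default `FALSE`).
#' @param retryBudget drawing attempts allowed per glyph before giving up.
#' @return A binary [PatternMatrix] (`prod(shape) x n`).
#' @export
generateSymbols <- function(n, shape = c(16L, 16L), seed = 1L,
                            strokeRange = c(2L, 5L), dMin = 8L,
                            includeSimilarPair = FALSE, retryBudget = 200L) {
  stopifnot(n >= 1L)
  shape <- as.integer(shape)
  M <- prod(shape)
  minActive <- max(6L, dMin)
  out <- withr::with_seed(seed, {
    acc <- matrix(0L, M, n)
    got <- 0L
    while (got < n) {
      ok <- FALSE
      for (try in seq_len(retryBudget)) {
        g <- imageToVec(randomGlyph(shape, strokeRange))
        if (sum(g) < minActive || sum(g) > 0.6 * M) next
        if (got > 0L) {
          dists <- colSums(abs(acc[, seq_len(got), drop = FALSE] - g))
          if (min(dists) < dMin) next
        }
        acc[, got + 1L] <- g
        got <- got + 1L
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf(
          "could not draw glyph %d with Hamming distance >= %d in %d tries",
          got + 1L, dMin, retryBudget
        ), call. = FALSE)
      }
    }
    if (includeSimilarPair && n >= 2L) {
      # near-duplicate of glyph 1 at exactly dMin flipped pixels
      for (try in seq_len(retryBudget)) {
        gg <- acc[, 1L]
        flip <- sample.int(M, dMin)
        gg[flip] <- 1L - gg[flip]
        dists <- colSums(abs(acc[, seq_len(n - 1L), drop = FALSE] - gg))
        if (min(dists) >= dMin) {
          acc[, n] <- gg
          break
        }
        if (try == retryBudget) {
          stop("could not place the near-duplicate pair", call. = FALSE)
        }
      }
    }
    acc
  })
  PatternMatrix(out * 1.0, imageShape = shape)
}

# ---- faces ----------------------------------------------------------------

#' @noRd
fillEllipse <- function(img, cr, cc, ry, rx, value) {
  rows <- (row(img) - 1) - cr
  cols <- (col(img) - 1) - cc
  inside <- (rows / ry)^2 + (cols / rx)^2 <= 1
  img[inside] <- value
  img
}

#' @noRd
drawFace <- function(shape, jitter) {
  h <- shape[1L]; w <- shape[2L]
  img <- matrix(0, h, w)
  j <- function(s) stats::runif(1, -s, s) * jitter
  cr <- (h - 1) / 2 + j(0.8)
  cc <- (w - 1) / 2 + j(0.8)
  ry <- 0.44 * h + j(1.2)
  rx <- 0.36 * w + j(1.2)
  skin <- 0.5 + j(0.08)
  img <- fillEllipse(img, cr, cc, ry, rx, skin)
  # gentle vertical shading so faces are not piecewise constant
  shade <- 0.06 * ((row(img) - 1) / (h - 1) - 0.5)
  img[img > 0] <- pmin(pmax(img[img > 0] + shade[img > 0], 0.2), 0.9)
  # eyes
  eyeRow <- 0.36 * h + j(0.8)
  eyeOff <- 0.18 * w + j(0.6)
  eyeR <- 1.4 + j(0.3) * 0.5
  eyeInt <- 0.06 + abs(j(0.02))
  img <- fillEllipse(img, eyeRow, cc - eyeOff, eyeR, eyeR * 1.2, eyeInt)
  img <- fillEllipse(img, eyeRow, cc + eyeOff, eyeR, eyeR * 1.2, eyeInt)
  # nose: short bright vertical bar
  noseTop <- round(0.44 * h + j(0.8))
  noseLen <- round(0.18 * h + abs(j(0.8)))
  noseCol <- round(cc + j(0.4))
  nr <- pmin(pmax(noseTop:(noseTop + noseLen), 0L), h - 1L)
  img[cbind(nr + 1L, noseCol + 1L)] <- 0.72 + j(0.05)
  # mouth: dark horizontal arc
  mouthRow <- 0.74 * h + j(0.8)
  mouthHw <- 0.13 * w + abs(j(1.0))
  mcols <- round(seq(cc - mouthHw, cc + mouthHw, by = 1))
  mrows <- round(mouthRow + 0.08 * abs(mcols - cc))
  ok <- mrows >= 0 & mrows < h & mcols >= 0 & mcols < w
  img[cbind(mrows[ok] + 1L, mcols[ok] + 1L)] <- 0.12 + abs(j(0.03))
  pmin(pmax(img, 0), 1)
}

#' Generate parametric face-like images
#'
#' Draws `n` grayscale face surrogates: a shaded oval with eyes, nose and
#' mouth whose geometry and intensities are jittered per face, mapped to
#' `[0, 1]`. These emulate the layout statistics of aligned frontal-face
#' photographs at small resolution.
#'
#' @param n number of faces.
#' @param shape image `(height, width)` (default `c(25, 25)`).
#' @param seed integer seed.
#' @param jitter geometric/intensity jitter scale (default 1; 0 gives
#'   identical faces).
#' @return A [PatternMatrix] (`prod(shape) x n`).
#' @export
generateFaces <- function(n, shape = c(25L, 25L), seed = 1L, jitter = 1) {
  stopifnot(n >= 1L)
  shape <- as.integer(shape)
  out <- withr::with_seed(seed, {
    vapply(seq_len(n), function(i) imageToVec(drawFace(shape, jitter)),
           numeric(prod(shape)))
  })
  PatternMatrix(matrix(out, nrow = prod(shape)), imageShape = shape)
}

#' Apply a deterministic alteration to a face image
#'
#' Overlays accessories or zeroes half-planes on a vectorized face:
#' `"sunglasses"` darkens the eye band, `"mustache"` darkens the band between
#' nose and mouth, `"both"` applies both, and the four `"occlude_*"` kinds
#' zero the corresponding half of the image (`floor(h/2)` rows or
#' `floor(w/2)` columns).
#'
#' @param x numeric pattern vector (row-major vectorized face).
#' @param shape image `(height, width)`.
#' @param kind one of `"sunglasses"`, `"mustache"`, `"both"`,
#'   `"occlude_top"`, `"occlude_bottom"`, `"occlude_left"`,
#'   `"occlude_right"`.
#' @return Altered pattern vector.
#' @export
applyAlteration <- function(x, shape = c(25L, 25L), kind) {
  shape <- as.integer(shape)
  h <- shape[1L]; w <- shape[2L]
  kinds <- c("sunglasses", "mustache", "both", "occlude_top",
             "occlude_bottom", "occlude_left", "occlude_right")
  if (!kind %in% kinds) {
    stop("unknown alteration kind: ", kind, call. = FALSE)
  }
  bandSet <- function(v, r0, r1, c0, c1, value) {
    img <- vecToImage(v, shape)
    img[(r0 + 1L):r1, (c0 + 1L):c1] <- value
    imageToVec(img)
  }
  eyeBand <- function(v) {
    bandSet(v, round(0.28 * h), round(0.46 * h),
            round(0.14 * w), round(0.86 * w), 0.05)
  }
  mustacheBand <- function(v) {
    bandSet(v, round(0.62 * h), round(0.72 * h),
            round(0.30 * w), round(0.70 * w), 0.08)
  }
  switch(kind,
    sunglasses = eyeBand(x),
    mustache = mustacheBand(x),
    both = mustacheBand(eyeBand(x)),
    occlude_top = occlude(x, shape, c(0L, 0L, h %/% 2L, w)),
    occlude_bottom = occlude(x, shape, c(h - h %/% 2L, 0L, h, w)),
    occlude_left = occlude(x, shape, c(0L, 0L, h, w %/% 2L)),
    occlude_right = occlude(x, shape, c(0L, w - w %/% 2L, h, w))
  )
}

# ---- natural-image-like patches -------------------------------------------

#' @noRd
radialFilter <- function(h, w, beta) {
  kr <- (seq_len(h) - 1) / h
  kr <- ifelse(kr > 0.5, kr - 1, kr)
  kc <- (seq_len(w) - 1) / w
  kc <- ifelse(kc > 0.5, kc - 1, kc)
  r <- sqrt(outer(kr^2, kc^2, "+"))
  f <- matrix(0, h, w)
  f[r > 0] <- r[r > 0]^(-beta / 2)
  f
}

#' Generate signed, centered natural-image-like patches
#'
#' Gaussian random fields with a radially `1/f^beta` power spectrum, with an
#' optional admixture of smoothed oriented step edges supplying the sparse
#' oriented structure characteristic of natural scenes (pure Gaussian fields
#' carry no such higher-order structure). Each patch is normalized to unit
#' standard deviation (when non-constant) and mean-centered exactly, ready
#' for [makeOnOff()].
#'
#' @param n number of patches.
#' @param shape patch `(height, width)` (default `c(16, 16)`).
#' @param beta spectral exponent (`>= 0`; default 2, the natural-image
#'   value).
#' @param seed integer seed.
#' @param edgeFraction fraction of patches receiving an oriented edge
#'   (default 0.5).
#' @param edgeContrast edge amplitude relative to the unit-variance
#'   background (default 1).
#' @return Signed numeric matrix (`prod(shape) x n`), per-patch mean 0.
#' @export
generatePatches <- function(n, shape = c(16L, 16L), beta = 2, seed = 1L,
                            edgeFraction = 0.5, edgeContrast = 1) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  stopifnot(n >= 1L)
  shape <- as.integer(shape)
  h <- shape[1L]; w <- shape[2L]
  filt <- radialFilter(h, w, beta)
  withr::with_seed(seed, {
    out <- matrix(0, h * w, n)
    rows0 <- row(filt) - 1
    cols0 <- col(filt) - 1
    for (i in seq_len(n)) {
      z <- matrix(stats::rnorm(h * w), h, w)
      f <- stats::fft(z) * filt
      patch <- Re(stats::fft(f, inverse = TRUE)) / (h * w)
      s <- stats::sd(patch)
      if (s > 0) patch <- patch / s
      if (stats::runif(1) < edgeFraction) {
        th <- stats::runif(1, 0, pi)
        offset <- stats::runif(1, -0.2, 0.2) * sqrt(h^2 + w^2)
        d <- (rows0 - (h - 1) / 2) * sin(th) +
          (cols0 - (w - 1) / 2) * cos(th) - offset
        patch <- patch + edgeContrast * tanh(d / 0.7)
      }
      patch <- patch - mean(patch)
      out[, i] <- imageToVec(patch)
    }
    out
  })
}
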