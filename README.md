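# mdcoding

Robust object codes by **maximal dependence capturing (MDC)**: non-negative,
dimension-expanded sparse dictionary learning plus non-negative l1 encoding.

## The scientific problem

Sensory systems recognize objects from inputs that are noisy, occluded, or
missing parts — without ever having been trained on the corrupted forms.
Classic efficient-coding models assign neurons to *independent* stimulus
features, which discards the relational structure that identifies an object
and makes invariant recognition hard. The MDC framework inverts this: each
representation unit captures a feature *combination* that is maximally
informative about specific objects. Two constraints produce such units
during an ordinary linear transformation:

* learning a non-negative basis with sparse non-negative codes,
  a blind source separation of the pattern matrix `X` (`M` input channels ×
  `N` objects):

  ```
  min_{Φ≥0, A≥0}  ½‖X − ΦA‖²_F + λ‖A‖₁        (dictionary learning)
  ```

* encoding any pattern `x` — clean or corrupted — with the same rule,
  non-negative basis pursuit:

  ```
  min_{a≥0}  ‖a‖₁   s.t.  ‖x − Φa‖₂ ≤ ε        (sparse encoding)
  ```

with the representation dimension `K` chosen larger than the input
dimension `M`. Atoms (columns of `Φ`) then converge to whole informative
structures, the codes are sparse and decorrelated, and the code of a
corrupted pattern is carried by the same units as the clean one — robust
identification without deep networks or corrupted training examples.

The package is for computational neuroscientists and vision researchers who
want to reproduce, probe, or extend this coding scheme: the learner and
encoder, a quantitative evaluation suite (redundancy, per-pixel KL
structure divergence, Z-scored specificity, identification,
sparsity, unit decorrelation, per-unit informativeness), corruption
simulators with a Monte-Carlo robustness pipeline, On/Off-channel
projective-field analysis with a simple/complex classifier, a PCA baseline,
and seeded generators of surrogate symbol / face / natural-patch datasets.

## Worked example

```r
library(mdcoding)

symbols <- generateSymbols(60, seed = 42)            # 16x16 binary glyphs
fit <- learnDictionary(symbols, K = 150, seed = 1,
                       maxIter = 80, innerIter = 30)
fit
#> MDCFit: K=150 atoms over 60 patterns; 65 outer iteration(s), converged
#>   final objective 218.198 at lambda 0.6164

mean(codeSparsity(codes(fit))) * 150                 # active units per symbol
#> [1] 2.5

# drop half the pixels of symbol 17, encode, and ask who it is
x  <- patterns(symbols)[, 17]
xc <- pixelDropout(x, keepCount = 128, seed = 7)
a  <- sparseEncode(as.vector(xc), dictionary(fit))
spec <- specificityZscore(as.vector(a), codes(fit), trueIndex = 17)
spec$argmax                                          # identified as symbol 17
#> [1] 17
round(spec$z[17], 2)                                 # z at the true identity
#> [1] 7.57

rec <- reconstruct(dictionary(fit), as.vector(a))
round(sum(rec * x) / sqrt(sum(rec^2) * sum(x^2)), 3) # recovers the whole glyph
#> [1] 0.986

round(unitCorrelation(codes(fit))$meanAbsOffDiagonal, 4)
#> [1] 0.0361
```

Even with 50% of the input deleted, the code still points at the right
object with a specificity z-score of 7.6, the linear reconstruction restores
the whole glyph (cosine 0.99 to the uncorrupted original), and the
representation units are nearly uncorrelated — an average off-diagonal
correlation magnitude of 0.036 across 150 units.

A command-line front end over the same functions is installed at
`inst/scripts/mdc.R` (`gen-data`, `learn`, `encode`, `corrupt`,
`montecarlo`, `metrics`, `pfields`), each run writing a manifest that makes
it re-executable.

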