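Package: mdcoding
Title: Maximal Dependence Capturing Codes for Robust Sensory Representation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns non-negative, dimension-expanded sparse dictionaries from
    finite sets of sensory patterns and encodes novel or corrupted patterns by
    non-negative l1 minimization. Representation units capture whole informative
    structures of individual objects (maximal dependence capturing) rather than
    independent features, which yields object codes that are robust to occlusion,
    pixel dropout and additive noise without training on corrupted examples.
    Includes an alternating non-negative sparse factorization learner, a
    basis-pursuit style encoder, quantitative evaluation of representation
    redundancy, specificity, decorrelation, per-unit informativeness and
    structural divergence, corruption simulators with a Monte-Carlo robustness
    pipeline, On/Off channel construction with projective-field extraction and
    simple/complex receptive-field classification, a PCA baseline, and seeded
    generators of synthetic symbol, face and natural-image-patch datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
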