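#' @rdname PatternMatrix-class
#' @aliases patterns,PatternMatrix-method
setMethod("patterns", "PatternMatrix", function(x) x@values)

#' @rdname Dictionary-class
#' @aliases atoms,Dictionary-method
setMethod("atoms", "Dictionary", function(x) x@atoms)

#' @rdname CodeMatrix-class
#' @aliases codes,CodeMatrix-method
setMethod("codes", "CodeMatrix", function(x) x@codes)

#' @rdname MDCFit-class
#' @aliases codes,MDCFit-method
setMethod("codes", "MDCFit", function(x) x@codes)

#' @rdname PatternMatrix-class
setMethod("imageShape", "PatternMatrix", function(x) x@imageShape)

#' @rdname Dictionary-class
setMethod("imageShape", "Dictionary", function(x) x@imageShape)

#' @rdname PatternMatrix-class
setMethod("channelMode", "PatternMatrix", function(x) x@channelMode)

#' @rdname Dictionary-class
setMethod("channelMode", "Dictionary", function(x) x@channelMode)

#' @rdname PatternMatrix-class
setMethod("nPatterns", "PatternMatrix", function(x) ncol(x@values))

#' @rdname CodeMatrix-class
setMethod("nPatterns", "CodeMatrix", function(x) ncol(x@codes))

#' @rdname Dictionary-class
setMethod("nAtoms", "Dictionary", function(x) ncol(x@atoms))

#' @rdname CodeMatrix-class
setMethod("nAtoms", "CodeMatrix", function(x) nrow(x@codes))

#' @rdname CodeMatrix-class
setMethod("binarizationThreshold", "CodeMatrix",
          function(x) x@binarizationThreshold)

#' @rdname MDCFit-class
setMethod("dictionary", "MDCFit", function(x) x@dictionary)

#' @rdname MDCFit-class
setMethod("objectiveTrace", "MDCFit", function(x) x@objectiveTrace)

#' @rdname PatternMatrix-class
#' @param ... unused
setMethod("dim", "PatternMatrix", function(x) dim(x@values))

#' @rdname Dictionary-class
setMethod("dim", "Dictionary", function(x) dim(x@atoms))

#' @rdname CodeMatrix-class
setMethod("dim", "CodeMatrix", function(x) dim(x@codes))

#' @export
as.matrix.PatternMatrix <- function(x, ...) x@values

#' @export
as.matrix.Dictionary <- function(x, ...) x@atoms

#' @export
as.matrix.CodeMatrix <- function(x, ...) x@codes

setMethod("show", "PatternMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "PatternMatrix: %d encoder(s) x %d pattern(s), image %dx%d, mode '%s'\n",
    d[1L], d[2L], object@imageShape[1L], object@imageShape[2L],
    object@channelMode
  ))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "Dictionary", function(object) {
  d <- dim(object@atoms)
  cat(sprintf(
    "Dictionary: %d atom(s) of dimension %d, image %dx%d, mode '%s'\n",
    d[2L], d[1L], object@imageShape[1L], object@imageShape[2L],
    object@channelMode
  ))
  cat(sprintf("  atom l2 norms in [%.4g, %.4g]\n",
              min(colNorms(object@atoms)), max(colNorms(object@atoms))))
})

setMethod("show", "CodeMatrix", function(object) {
  d <- dim(object@codes)
  frac <- mean(object@codes > object@binarizationThreshold)
  cat(sprintf(
    "CodeMatrix: %d unit(s) x %d pattern(s), threshold %.4g, mean l0 %.3f\n",
    d[1L], d[2L], object@binarizationThreshold, frac
  ))
})

setMethod("show", "MDCFit", function(object) {
  cat(sprintf(
    "MDCFit: K=%d atoms over %d patterns; %d outer iteration(s), %s\n",
    nAtoms(object@dictionary), nPatterns(object@codes), object@iterations,
    if (object@converged) "converged" else "stopped at maxIter"
  ))
  tr <- object@objectiveTrace
  if (nrow(tr) > 0L) {
    cat(sprintf("  final objective %.6g at lambda %.4g\n",
                tr$objectiveAfter[nrow(tr)], tr$lambda[nrow(tr)]))
  }
})
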