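#' @rdname PatternMatrix-class
#' @param object,x a package object
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' @rdname Dictionary-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname CodeMatrix-class
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))

#' @rdname PatternMatrix-class
#' @export
setGeneric("imageShape", function(x) standardGeneric("imageShape"))

#' @rdname PatternMatrix-class
#' @export
setGeneric("channelMode", function(x) standardGeneric("channelMode"))

#' @rdname PatternMatrix-class
#' @export
setGeneric("nPatterns", function(x) standardGeneric("nPatterns"))

#' @rdname Dictionary-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname CodeMatrix-class
#' @export
setGeneric("binarizationThreshold",
           function(x) standardGeneric("binarizationThreshold"))

#' @rdname MDCFit-class
#' @export
setGeneric("dictionary", function(x) standardGeneric("dictionary"))

#' @rdname MDCFit-class
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
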