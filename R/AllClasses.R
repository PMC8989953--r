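#' PatternMatrix: a set of vectorized non-negative input patterns
#'
#' Container for an `M x N` non-negative matrix whose columns are row-major
#' vectorizations of `N` images (or other non-negative sensory patterns) of
#' `M` primary encoder responses. In `"onoff"` mode the rows hold the
#' rectified On channel stacked above the rectified Off channel, so `M` is
#' twice the pixel count.
#'
#' @slot values numeric matrix, `M x N`, all entries finite and `>= 0`.
#' @slot imageShape integer vector `(height, width)`; `height * width`
#'   equals `M` (`"plain"`) or `M / 2` (`"onoff"`).
#' @slot channelMode `"plain"` or `"onoff"`.
#'
#' @seealso [PatternMatrix()] for the user constructor.
#' @exportClass PatternMatrix
setClass("PatternMatrix",
  representation(
    values = "matrix",
    imageShape = "integer",
    channelMode = "character"
  )
)

setValidity("PatternMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (ncol(v) < 1L) return("need at least one pattern column")
  if (!all(is.finite(v))) return("values contain non-finite entries")
  if (any(v < 0)) return("values contain negative entries")
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L)) {
    return("imageShape must be two positive integers (height, width)")
  }
  if (!object@channelMode %in% c("plain", "onoff")) {
    return("channelMode must be 'plain' or 'onoff'")
  }
  m <- nrow(v)
  npix <- prod(object@imageShape)
  if (object@channelMode == "plain" && npix != m) {
    return("height * width must equal nrow(values) in plain mode")
  }
  if (object@channelMode == "onoff") {
    if (m %% 2L != 0L) return("onoff mode requires an even number of rows")
    if (npix != m / 2L) {
      return("height * width must equal nrow(values)/2 in onoff mode")
    }
  }
  TRUE
})

#' Dictionary: learned non-negative basis of projective fields
#'
#' An `M x K` non-negative matrix whose columns (atoms) are the tuning /
#' projective fields of `K` representation units, in the same vectorization
#' and channel convention as the [PatternMatrix] it was learned from.
#'
#' @slot atoms numeric matrix, `M x K`, entries finite and `>= 0`.
#' @slot imageShape integer `(height, width)`.
#' @slot channelMode `"plain"` or `"onoff"`.
#'
#' @exportClass Dictionary
setClass("Dictionary",
  representation(
    atoms = "matrix",
    imageShape = "integer",
    channelMode = "character"
  )
)

setValidity("Dictionary", function(object) {
  a <- object@atoms
  if (!is.numeric(a)) return("atoms must be a numeric matrix")
  if (ncol(a) < 1L) return("need at least one atom")
  if (!all(is.finite(a))) return("atoms contain non-finite entries")
  if (any(a < 0)) return("atoms contain negative entries")
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L)) {
    return("imageShape must be two positive integers (height, width)")
  }
  if (!object@channelMode %in% c("plain", "onoff")) {
    return("channelMode must be 'plain' or 'onoff'")
  }
  m <- nrow(a)
  npix <- prod(object@imageShape)
  if (object@channelMode == "plain" && npix != m) {
    return("height * width must equal nrow(atoms) in plain mode")
  }
  if (object@channelMode == "onoff" && (m %% 2L != 0L || npix != m / 2L)) {
    return("onoff mode requires nrow(atoms) = 2 * height * width")
  }
  TRUE
})

#' CodeMatrix: sparse non-negative representations
#'
#' A `K x N` non-negative matrix whose columns are the representations of `N`
#' patterns in a `K`-unit basis, together with the Heaviside binarization
#' threshold used for l0 / activation-probability statistics.
#'
#' @slot codes numeric matrix, `K x N`, entries finite and `>= 0`.
#' @slot binarizationThreshold single numeric `>= 0`; an entry counts as
#'   active when strictly greater than this value.
#' @slot metadata list of optional per-encoding details (residuals,
#'   feasibility flags, the epsilon used).
#'
#' @exportClass CodeMatrix
setClass("CodeMatrix",
  representation(
    codes = "matrix",
    binarizationThreshold = "numeric",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("CodeMatrix", function(object) {
  a <- object@codes
  if (!is.numeric(a)) return("codes must be a numeric matrix")
  if (!all(is.finite(a))) return("codes contain non-finite entries")
  if (any(a < 0)) return("codes contain negative entries")
  th <- object@binarizationThreshold
  if (length(th) != 1L || !is.finite(th) || th < 0) {
    return("binarizationThreshold must be a single finite value >= 0")
  }
  TRUE
})

#' MDCFit: result of dictionary learning
#'
#' Bundles the learned [Dictionary], the training [CodeMatrix], the
#' per-iteration objective trace and the configuration/seed needed to
#' reproduce the run.
#'
#' @slot dictionary learned [Dictionary].
#' @slot codes training [CodeMatrix].
#' @slot objectiveTrace data.frame with one row per outer iteration:
#'   `iteration`, `lambda`, `objectiveBefore`, `objectiveAfter`, `reseeded`.
#' @slot config list echo of the learning configuration.
#' @slot converged logical.
#' @slot iterations integer, outer iterations performed.
#'
#' @exportClass MDCFit
setClass("MDCFit",
  representation(
    dictionary = "Dictionary",
    codes = "CodeMatrix",
    objectiveTrace = "data.frame",
    config = "list",
    converged = "logical",
    iterations = "integer"
  )
)

#' Construct a PatternMatrix
#'
#' @param values numeric matrix (`M x N`) of non-negative pattern columns, or
#'   a numeric vector for a single pattern.
#' @param imageShape integer `(height, width)` of the underlying image.
#' @param channelMode `"plain"` (default) or `"onoff"`.
#' @return A [PatternMatrix] object.
#' @examples
#' pm <- PatternMatrix(matrix(runif(32), 16, 2), imageShape = c(4, 4))
#' nPatterns(pm)
#' @export
PatternMatrix <- function(values, imageShape, channelMode = c("plain", "onoff")) {
  channelMode <- match.arg(channelMode)
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  new("PatternMatrix",
    values = values,
    imageShape = as.integer(imageShape),
    channelMode = channelMode
  )
}

#' Construct a Dictionary
#'
#' @param atoms numeric matrix (`M x K`) of non-negative atom columns.
#' @param imageShape integer `(height, width)`.
#' @param channelMode `"plain"` or `"onoff"`.
#' @return A [Dictionary] object.
#' @export
Dictionary <- function(atoms, imageShape, channelMode = c("plain", "onoff")) {
  channelMode <- match.arg(channelMode)
  if (is.vector(atoms)) atoms <- matrix(atoms, ncol = 1L)
  new("Dictionary",
    atoms = atoms,
    imageShape = as.integer(imageShape),
    channelMode = channelMode
  )
}

#' Construct a CodeMatrix
#'
#' @param codes numeric matrix (`K x N`) of non-negative representations.
#' @param binarizationThreshold Heaviside threshold for l0 statistics;
#'   defaults to `1e-3 * max(codes)`.
#' @param metadata optional list of encoding details.
#' @return A [CodeMatrix] object.
#' @export
CodeMatrix <- function(codes, binarizationThreshold = NULL, metadata = list()) {
  if (is.vector(codes)) codes <- matrix(codes, ncol = 1L)
  if (is.null(binarizationThreshold)) {
    binarizationThreshold <- defaultThreshold(codes)
  }
  new("CodeMatrix",
    codes = codes,
    binarizationThreshold = binarizationThreshold,
    metadata = metadata
  )
}
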