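# Persistence: delimited-text matrices, PGM/PNG images, and JSON-manifested
# bundles for pattern sets and learned models. All on-disk formats are plain
# text or standard image files so runs stay inspectable and portable.

#' Write / read a dense numeric matrix as CSV
#'
#' Plain comma-separated values, no header, full double precision.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `readMatrixCSV` returns a numeric matrix.
#' @export
writeMatrixCSV <- function(m, path) {
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeMatrixCSV
#' @export
readMatrixCSV <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              colClasses = "numeric"))
}

#' Write / read an 8-bit grayscale PGM image
#'
#' Portable graymap, plain (P2) or binary (P5) flavor. Intensities in
#' `[0, 1]` map linearly to `0..255`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path.
#' @param ascii write plain-text P2 (default) instead of binary P5.
#' @return `readPGM` returns a numeric matrix in `[0, 1]`.
#' @export
writePGM <- function(img, path, ascii = TRUE) {
  vals <- round(pmin(pmax(img, 0), 1) * 255)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(img), nrow(img)), "255"), con)
    writeBin(as.integer(t(vals)), con, size = 1L)
  }
  invisible(path)
}

#' @rdname writePGM
#' @export
readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break
        next
      }
      tok <- paste0(tok, ch)
    }
    tok
  }
  magic <- readToken()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  w <- as.integer(readToken())
  h <- as.integer(readToken())
  maxval <- as.integer(readToken())
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
    img <- matrix(vals, nrow = h, byrow = TRUE)
  } else {
    raw <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
    img <- matrix(raw, nrow = h, byrow = TRUE)
  }
  img / maxval
}

#' Write / read a grayscale image (PNG or PGM by extension)
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path path ending in `.png` or `.pgm`.
#' @return `readImageFile` returns a numeric matrix in `[0, 1]` (color PNGs
#'   are converted to luminance).
#' @export
writeImageFile <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(img, 0), 1)
  switch(ext,
    png = png::writePNG(img, path),
    pgm = writePGM(img, path),
    stop("unsupported image extension: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' @rdname writeImageFile
#' @export
readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      img <- 0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    }
    return(img)
  }
  if (ext == "pgm") {
    return(readPGM(path))
  }
  stop("unsupported image extension: ", ext, call. = FALSE)
}

#' Save / load a PatternMatrix bundle
#'
#' A directory with `values.csv` and a `manifest.json` echoing the image
#' shape and channel mode.
#'
#' @param x a [PatternMatrix].
#' @param dir directory (created if needed).
#' @return `loadPatternMatrix` returns the [PatternMatrix].
#' @export
savePatternMatrix <- function(x, dir) {
  stopifnot(is(x, "PatternMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixCSV(patterns(x), file.path(dir, "values.csv"))
  jsonlite::write_json(
    list(kind = "PatternMatrix", imageShape = imageShape(x),
         channelMode = channelMode(x), dims = dim(x)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname savePatternMatrix
#' @export
loadPatternMatrix <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  PatternMatrix(readMatrixCSV(file.path(dir, "values.csv")),
                imageShape = man$imageShape, channelMode = man$channelMode)
}

#' Save / load a learned model bundle
#'
#' A directory holding the dictionary atoms (`atoms.csv`), the training
#' codes (`codes.csv`), the objective trace (`objective_trace.csv`) and a
#' `manifest.json` with image shape, channel mode, configuration and seed —
#' everything needed to reproduce or reuse the run.
#'
#' @param fit an [MDCFit].
#' @param dir directory (created if needed).
#' @return `loadModel` returns the [MDCFit].
#' @export
saveModel <- function(fit, dir) {
  stopifnot(is(fit, "MDCFit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dictionary(fit)
  writeMatrixCSV(atoms(d), file.path(dir, "atoms.csv"))
  writeMatrixCSV(codes(codes(fit)), file.path(dir, "codes.csv"))
  utils::write.csv(objectiveTrace(fit),
                   file.path(dir, "objective_trace.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(kind = "MDCFit", imageShape = imageShape(d),
         channelMode = channelMode(d),
         binarizationThreshold = binarizationThreshold(codes(fit)),
         config = fit@config, converged = fit@converged,
         iterations = fit@iterations),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  d <- Dictionary(readMatrixCSV(file.path(dir, "atoms.csv")),
                  imageShape = man$imageShape, channelMode = man$channelMode)
  cm <- CodeMatrix(readMatrixCSV(file.path(dir, "codes.csv")),
                   binarizationThreshold = man$binarizationThreshold)
  new("MDCFit",
    dictionary = d, codes = cm,
    objectiveTrace = utils::read.csv(file.path(dir, "objective_trace.csv")),
    config = as.list(man$config),
    converged = isTRUE(man$converged),
    iterations = as.integer(man$iterations)
  )
}

#' Export every column of a pattern set or dictionary as images
#'
#' @param x a [PatternMatrix] or [Dictionary].
#' @param dir output directory.
#' @param format `"png"` or `"pgm"`.
#' @param prefix file-name prefix.
#' @return Invisibly, the written paths. Atom/pattern intensities are
#'   rescaled to `[0, 1]` by the matrix maximum; On/Off objects are exported
#'   as signed projective fields mapped to mid-gray zero.
#' @export
exportImages <- function(x, dir, format = c("png", "pgm"), prefix = "im") {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is(x, "Dictionary") && channelMode(x) == "onoff") {
    fields <- projectiveFields(x)
    mx <- max(abs(unlist(fields)), 1e-12)
    imgs <- lapply(fields, function(f) (f / mx + 1) / 2)
  } else {
    v <- if (is(x, "Dictionary")) atoms(x) else patterns(x)
    shape <- imageShape(x)
    mx <- max(v, 1e-12)
    imgs <- lapply(seq_len(ncol(v)), function(j) vecToImage(v[, j] / mx, shape))
  }
  paths <- vapply(seq_along(imgs), function(j) {
    p <- file.path(dir, sprintf("%s_%04d.%s", prefix, j, format))
    writeImageFile(imgs[[j]], p)
    p
  }, character(1L))
  invisible(paths)
}
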