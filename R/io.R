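#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF image as a numeric matrix normalised to
#' \eqn{[0, 1]} by the dtype maximum (both readers already divide by it;
#' no min-max stretching is applied, preserving contrast-invariance
#' properties). Colour images are converted to grayscale by channel
#' averaging.
#'
#' @param path file path ending in .png, .tif or .tiff
#' @return numeric matrix (rows = image rows, row 1 at the top)
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  img
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground is written as 255, background as 0.
#'
#' @param mask binary matrix
#' @param path output path (.png)
#' @return invisibly, `path`
#' @export
writeMask <- function(mask, path) {
  mask <- asBinaryMask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write a numeric map as 32-bit float TIFF
#'
#' @param map numeric matrix
#' @param path output path (.tif)
#' @return invisibly, `path`
#' @export
writeFloatMap <- function(map, path) {
  tiff::writeTIFF(map, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read seed coordinates from JSON
#'
#' Seeds are stored as a JSON list of objects with 0-based `row` and `col`
#' pixel coordinates (row 0 at the top); they are converted to the 1-based
#' (row, col) convention used by the R functions.
#'
#' @param path JSON file
#' @return integer matrix, one seed per row, 1-based
#' @export
readSeeds <- function(path) {
  js <- jsonlite::fromJSON(path)
  if (is.data.frame(js)) {
    seeds <- cbind(js$row, js$col)
  } else {
    seeds <- do.call(rbind, lapply(js, function(s) c(s$row, s$col)))
  }
  if (is.null(seeds) || ncol(seeds) != 2L)
    stop("seed file must be a JSON list of {row, col} objects")
  seedMatrix(seeds + 1L)
}
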