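#' RGB field image
#'
#' Container for an H x W x 3 RGB raster with an optional spatial
#' calibration. Channel intensities are integers in \[0, 255\] (stored as
#' numeric for arithmetic safety); `gsd_cm` is the ground sampling
#' distance, i.e. the physical size in centimetres of one pixel side.
#'
#' @param pixels numeric H x W x 3 array, values in \[0, 255\]
#'   (dimension 3 is red, green, blue).
#' @param gsd_cm positive ground sampling distance in cm per pixel
#'   (default 0.5, typical of a low-altitude UAV RGB survey).
#' @return an object of class `rgb_image`.
#' @examples
#' px <- array(c(120, 60, 100, 130, 80, 55), dim = c(1, 2, 3))
#' img <- rgb_image(px)
#' dim(img$pixels)
#' @export
rgb_image <- function(pixels, gsd_cm = 0.5) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be an H x W x 3 array (red, green, blue channels)")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel intensities must lie in [0, 255] with no missing values")
  if (!is.numeric(gsd_cm) || length(gsd_cm) != 1L || !is.finite(gsd_cm) ||
      gsd_cm <= 0)
    stop("'gsd_cm' must be a single positive number")
  structure(list(pixels = pixels, gsd_cm = gsd_cm), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px, gsd %.3g cm/px (%.2f x %.2f m)\n",
              d[1], d[2], x$gsd_cm,
              d[1] * x$gsd_cm / 100, d[2] * x$gsd_cm / 100))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)[1:2]

#' Read an RGB image from PNG or TIFF
#'
#' Reads an 8-bit (or normalised) raster and returns an [rgb_image()].
#' Greyscale files are replicated across the three channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path; format inferred from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @param gsd_cm ground sampling distance in cm per pixel.
#' @return an `rgb_image`.
#' @export
read_rgb_image <- function(path, gsd_cm = 0.5) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF files")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: '", ext, "' (use PNG or TIFF)")
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  rgb_image(round(raw * 255), gsd_cm = gsd_cm)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Vegetation pixels (1) are written white (255), background (0) black.
#'
#' @param mask binary matrix of 0/1 as produced by [segment_vegetation()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}
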