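#' Excess Green vegetation index
#'
#' Computes the Excess Green index, ExG = 2G - R - B, per pixel in signed
#' arithmetic. Green canopy scores high, soil near zero or below; the
#' result is a signed greyscale suitable for automatic thresholding with
#' [otsu_threshold()].
#'
#' @param image an [rgb_image()].
#' @return a matrix of class `index_image` with attributes `index_name`
#'   (`"ExG"`) and `gsd_cm`. Values lie in \[-510, 510\].
#' @seealso [compute_exg_exr()], [segment_vegetation()]
#' @examples
#' img <- rgb_image(array(c(50, 120, 30), dim = c(1, 1, 3)))
#' compute_exg(img)[1, 1]  # 2*120 - 50 - 30 = 160
#' @export
compute_exg <- function(image) {
  image <- as_rgb_image(image)
  p <- image$pixels
  v <- 2 * p[, , 2] - p[, , 1] - p[, , 3]
  index_image(matrix(v, dim(p)[1], dim(p)[2]), "ExG", image$gsd_cm)
}

#' Excess Green minus Excess Red vegetation index
#'
#' Computes ExG - ExR = 3G - 2.4R - B per pixel. By construction plant
#' pixels map to positive values and soil to negative values, so the fixed
#' threshold 0 can binarise the result directly
#' (`segment_vegetation(method = "zero")`).
#'
#' @inheritParams compute_exg
#' @return an `index_image` matrix (`index_name = "ExG-ExR"`), values in
#'   \[-867, 765\].
#' @examples
#' img <- rgb_image(array(c(50, 120, 30), dim = c(1, 1, 3)))
#' compute_exg_exr(img)[1, 1]  # 3*120 - 2.4*50 - 30 = 210
#' @export
compute_exg_exr <- function(image) {
  image <- as_rgb_image(image)
  p <- image$pixels
  v <- 3 * p[, , 2] - 2.4 * p[, , 1] - p[, , 3]
  index_image(matrix(v, dim(p)[1], dim(p)[2]), "ExG-ExR", image$gsd_cm)
}

index_image <- function(values, index_name, gsd_cm) {
  structure(values, index_name = index_name, gsd_cm = gsd_cm,
            class = c("index_image", "matrix", "array"))
}

as_rgb_image <- function(image) {
  if (inherits(image, "rgb_image")) return(image)
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L)
    return(rgb_image(image))
  stop("expected an 'rgb_image' or an H x W x 3 array")
}

#' @export
print.index_image <- function(x, ...) {
  cat(sprintf("<index_image> %s, %d x %d px, range [%.4g, %.4g]\n",
              attr(x, "index_name"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}
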