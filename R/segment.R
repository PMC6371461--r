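#' Otsu threshold of a vegetation-index image
#'
#' Automatic histogram thresholding maximising between-class variance.
#' Because vegetation indices are signed reals rather than 8-bit counts,
#' the values are binned into a 256-bin histogram over their observed
#' \[min, max\] range, Otsu's criterion is maximised in bin space (lowest
#' bin wins ties), and the cut is mapped back to the value scale as the
#' midpoint between the largest observed value at or below the cut and the
#' smallest observed value above it. With that convention
#' `value > threshold` reproduces the bin classification exactly.
#'
#' @param index an `index_image` (or any numeric matrix) with at least two
#'   distinct values.
#' @param n_bins number of histogram bins (default 256, the classical
#'   8-bit resolution).
#' @return the threshold, a single number: pixels strictly above it belong
#'   to the high-intensity (vegetation) class.
#' @references Otsu, N. (1979) A threshold selection method from
#'   gray-level histograms. IEEE Trans. Syst. Man Cybern. 9, 62-66.
#' @export
otsu_threshold <- function(index, n_bins = 256L) {
  v <- as.numeric(index)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("index image has no finite values")
  mn <- min(v); mx <- max(v)
  if (mn == mx)
    stop("degenerate histogram: the index image is constant (all values = ",
         format(mn), "); Otsu thresholding needs at least two distinct values")
  bw <- (mx - mn) / n_bins
  bin <- pmin(floor((v - mn) / bw), n_bins - 1L)  # 0-based bin index
  counts <- as.numeric(tabulate(bin + 1L, nbins = n_bins))
  # between-class variance for every cut t: background = bins 0..t
  mids <- seq_len(n_bins) - 1L
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * mids)
  n <- w0[n_bins]; stot <- s0[n_bins]
  t_all <- seq_len(n_bins - 1L)            # cut after bin t-1 (1-based)
  w0c <- w0[t_all]; w1c <- n - w0c
  valid <- w0c > 0 & w1c > 0
  mu0 <- s0[t_all] / w0c
  mu1 <- (stot - s0[t_all]) / w1c
  sigma_b <- ifelse(valid, w0c * w1c * (mu0 - mu1)^2, -Inf)
  t_best <- which.max(sigma_b) - 1L        # 0-based cut bin; lowest tie wins
  # map back: midpoint between the classes' nearest observed values
  lo <- max(v[bin <= t_best])
  hi <- min(v[bin > t_best])
  (lo + hi) / 2
}

#' Binarise a vegetation-index image
#'
#' Separates canopy from soil. With `method = "otsu"` the threshold is
#' found by [otsu_threshold()] (the usual pairing with the ExG index);
#' with `method = "zero"` the fixed threshold 0 is used, relying on the
#' ExG-ExR index mapping plant pixels to positive values. Vegetation is
#' the class strictly above the threshold.
#'
#' @param index an `index_image` or numeric matrix.
#' @param method `"otsu"` or `"zero"`.
#' @return an integer 0/1 matrix of class `binary_mask` (1 = vegetation)
#'   carrying the `gsd_cm` attribute of its source, plus a `threshold`
#'   attribute.
#' @examples
#' img <- rgb_image(array(c(200, 40, 90, 180, 70, 60), dim = c(1, 2, 3)))
#' segment_vegetation(compute_exg_exr(img), method = "zero")
#' @export
segment_vegetation <- function(index, method = c("otsu", "zero")) {
  method <- match.arg(method)
  thr <- if (method == "otsu") otsu_threshold(index) else 0
  m <- matrix(as.integer(as.matrix(index) > thr), nrow(index), ncol(index))
  structure(m, gsd_cm = attr(index, "gsd_cm"), threshold = thr,
            method = method, class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d vegetation px (%.1f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

#' Segmentation quality factor (intersection over union)
#'
#' Agreement between a predicted and a reference binary vegetation mask,
#' following the ATRWG criterion: Q = |P and B| / |P or B| over vegetation
#' pixels. Q is 1.0 exactly when the masks are identical and non-empty and
#' 0 when they are disjoint.
#'
#' @param predicted,reference binary 0/1 matrices of identical dimensions.
#' @return Q, a number in \[0, 1\].
#' @export
quality_factor <- function(predicted, reference) {
  p <- as.matrix(predicted) != 0
  r <- as.matrix(reference) != 0
  if (!identical(dim(p), dim(r)))
    stop("mask dimensions differ: ", paste(dim(p), collapse = "x"),
         " vs ", paste(dim(r), collapse = "x"))
  union <- sum(p | r)
  if (union == 0L)
    stop("quality factor undefined: both masks are empty (0/0)")
  sum(p & r) / union
}
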