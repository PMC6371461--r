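#' Agreement between estimated and reference measurements
#'
#' Ordinary least-squares fit of estimated on reference values plus the
#' two agreement statistics used to validate image-based emergence
#' against manual counts: r-squared (squared Pearson correlation) and
#' RMSE. RMSE is computed on the raw paired differences
#' (estimated - reference), i.e. deviation from the ideal 1:1 line, not
#' on regression residuals, so a constant offset shows up in RMSE even
#' when r-squared is 1.
#'
#' @param estimated,reference numeric vectors in the same units,
#'   length >= 3.
#' @return list with `r2`, `rmse`, `slope`, `intercept`, `n`.
#' @export
regress_paired <- function(estimated, reference) {
  estimated <- as.numeric(estimated); reference <- as.numeric(reference)
  if (length(estimated) != length(reference))
    stop("'estimated' and 'reference' lengths differ")
  if (length(estimated) < 3L) stop("need at least 3 paired measurements")
  if (!all(is.finite(estimated)) || !all(is.finite(reference)))
    stop("measurements must be finite")
  if (stats::sd(reference) == 0)
    stop("reference values are constant; regression undefined")
  fit <- stats::lm(estimated ~ reference)
  list(r2 = unname(stats::cor(estimated, reference)^2),
       rmse = sqrt(mean((estimated - reference)^2)),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(estimated))
}

#' Compare segmentation methods against reference masks
#'
#' Runs each segmentation method on each ROI image and scores it with the
#' quality factor Q ([quality_factor()]) against the ROI's reference
#' mask. A method that fails on a given ROI (e.g. a degenerate histogram)
#' is recorded as NA for that ROI rather than aborting the comparison.
#'
#' @param rois list of `list(image = rgb_image, reference = mask)` pairs,
#'   optionally named.
#' @param methods character vector of [segment_field()] method names, or
#'   a named list mixing method names and functions `image -> mask`.
#' @return list with `per_roi` (data.frame `roi`, `method`, `Q`) and
#'   `means` (named mean Q per method over the ROIs where it succeeded).
#' @export
compare_segmentations <- function(rois,
                                  methods = c("exg_otsu", "exg_exr_zero")) {
  if (length(rois) == 0L) stop("no ROIs supplied")
  roi_names <- names(rois)
  if (is.null(roi_names)) roi_names <- as.character(seq_along(rois))
  if (is.character(methods)) methods <- as.list(methods)
  method_names <- names(methods)
  if (is.null(method_names)) method_names <- rep("", length(methods))
  for (k in seq_along(methods)) {
    if (method_names[k] == "")
      method_names[k] <- if (is.character(methods[[k]])) methods[[k]]
                         else paste0("method_", k)
  }
  rows <- list()
  for (i in seq_along(rois)) {
    for (k in seq_along(methods)) {
      seg <- methods[[k]]
      run <- if (is.character(seg))
        function(img) segment_field(img, seg) else seg
      q <- tryCatch(
        quality_factor(run(rois[[i]]$image), rois[[i]]$reference),
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(roi = roi_names[i], method = method_names[k], Q = q)
    }
  }
  per_roi <- do.call(rbind, rows)
  means <- tapply(per_roi$Q, per_roi$method, mean, na.rm = TRUE)
  list(per_roi = per_roi, means = means[method_names])
}
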