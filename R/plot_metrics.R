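#' Define a plot region of interest
#'
#' A plot ROI is an axis-aligned rectangle in 0-based pixel coordinates
#' (`x0` = column, `y0` = row of the top-left corner), optionally refined
#' by an arbitrary polygon, together with the number of seeds sown in the
#' plot (the denominator of the emergence rate).
#'
#' @param roi_id identifier.
#' @param x0,y0 top-left corner, 0-based pixels.
#' @param width,height extent in pixels.
#' @param seeds_sown positive integer, seeds sown in this plot.
#' @param polygon optional n x 2 matrix of (x, y) vertices, 0-based;
#'   pixels outside it are zeroed on cropping.
#' @return an object of class `plot_roi`.
#' @export
plot_roi <- function(roi_id, x0, y0, width, height, seeds_sown,
                     polygon = NULL) {
  if (!is.numeric(seeds_sown) || length(seeds_sown) != 1L || seeds_sown <= 0)
    stop("'seeds_sown' must be a positive count")
  if (width < 1 || height < 1) stop("ROI must span at least one pixel")
  structure(list(roi_id = roi_id, x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height),
                 seeds_sown = as.integer(seeds_sown), polygon = polygon),
            class = "plot_roi")
}

#' Read ROI definitions from CSV
#'
#' One rectangle per row with columns
#' `roi_id, x0, y0, width, height, seeds_sown`.
#'
#' @param path CSV path.
#' @return list of [plot_roi()] objects.
#' @export
read_roi_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("roi_id", "x0", "y0", "width", "height", "seeds_sown")
  missing_cols <- setdiff(need, colnames(d))
  if (length(missing_cols))
    stop("ROI CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(d)), function(i)
    plot_roi(d$roi_id[i], d$x0[i], d$y0[i], d$width[i], d$height[i],
             d$seeds_sown[i]))
}

#' Crop an image (or mask) to a plot ROI
#'
#' Restricts the raster to the ROI rectangle (clipped to the image); for a
#' polygonal ROI, pixels inside the rectangle but outside the polygon are
#' zeroed. The spatial calibration is inherited.
#'
#' @param image an `rgb_image`, or a matrix (index image or mask).
#' @param roi a [plot_roi()].
#' @return the cropped object, same class as the input.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(inherits(roi, "plot_roi"))
  is_img <- inherits(image, "rgb_image")
  d <- if (is_img) dim(image$pixels)[1:2] else dim(image)
  rows <- intersect(seq_len(d[1]), (roi$y0 + 1):(roi$y0 + roi$height))
  cols <- intersect(seq_len(d[2]), (roi$x0 + 1):(roi$x0 + roi$width))
  if (length(rows) == 0L || length(cols) == 0L)
    stop("ROI '", roi$roi_id, "' does not intersect the image")
  keep <- NULL
  if (!is.null(roi$polygon)) {
    g <- expand.grid(row = rows - 1L, col = cols - 1L)
    inside <- point_in_polygon(g$col, g$row,
                               roi$polygon[, 1], roi$polygon[, 2])
    keep <- matrix(inside, length(rows), length(cols))
  }
  if (is_img) {
    px <- image$pixels[rows, cols, , drop = FALSE]
    if (!is.null(keep)) for (ch in 1:3) px[, , ch][!keep] <- 0
    rgb_image(px, gsd_cm = image$gsd_cm)
  } else {
    out <- image[rows, cols, drop = FALSE]
    if (!is.null(keep)) out[!keep] <- 0
    attributes(out) <- c(attributes(out),
                         attributes(image)[setdiff(names(attributes(image)),
                                                   c("dim", "dimnames"))])
    out
  }
}

# even-odd ray casting, vectorised over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Emergence rate
#'
#' Percentage of sown seeds that produced a counted plant.
#'
#' @param estimated_plants non-negative plant count for the plot.
#' @param seeds_sown positive number of seeds sown.
#' @return emergence rate in percent.
#' @examples
#' emergence_rate(135, 270)  # 50
#' @export
emergence_rate <- function(estimated_plants, seeds_sown) {
  if (any(seeds_sown <= 0)) stop("'seeds_sown' must be positive")
  if (any(estimated_plants < 0)) stop("plant counts cannot be negative")
  100 * estimated_plants / seeds_sown
}

#' Canopy cover totals
#'
#' Total canopy cover of a plot (sum of object pixel areas in physical
#' units) and the average canopy cover per plant (total divided by the
#' total estimated plant number).
#'
#' @param objects list of `plant_object`s, or a numeric vector of object
#'   pixel areas.
#' @param counts integer predicted plant count per object (each >= 1).
#' @param gsd_cm ground sampling distance, cm per pixel.
#' @return list with `total_canopy_cm2` and `mean_cover_per_plant_cm2`.
#' @export
canopy_metrics <- function(objects, counts, gsd_cm) {
  px <- object_pixel_areas(objects)
  counts <- as.integer(counts)
  if (length(px) == 0L) stop("no plant objects supplied")
  if (length(counts) != length(px))
    stop("'counts' must be parallel to 'objects'")
  if (any(counts < 1L)) stop("every object must hold at least one plant")
  total <- sum(px) * gsd_cm^2
  list(total_canopy_cm2 = total,
       mean_cover_per_plant_cm2 = total / sum(counts))
}

#' Emergence uniformity (coefficient of variation)
#'
#' For each object the average canopy cover per plant is its area divided
#' by its predicted plant count; uniformity is the coefficient of
#' variation of these per-object values across the plot (sample standard
#' deviation over mean, in percent). Lower CV means more uniform
#' emergence. Invariant to the spatial calibration and to uniform scaling
#' of all areas.
#'
#' @inheritParams canopy_metrics
#' @return CV in percent.
#' @export
uniformity_cv <- function(objects, counts, gsd_cm = 1) {
  px <- object_pixel_areas(objects)
  counts <- as.integer(counts)
  if (length(px) < 2L)
    stop("uniformity CV needs at least 2 plant objects")
  if (length(counts) != length(px))
    stop("'counts' must be parallel to 'objects'")
  if (any(counts < 1L)) stop("every object must hold at least one plant")
  per_plant <- px * gsd_cm^2 / counts
  m <- mean(per_plant)
  if (m == 0) stop("mean cover per plant is zero; CV undefined")
  100 * stats::sd(per_plant) / m
}

object_pixel_areas <- function(objects) {
  if (is.numeric(objects)) return(as.numeric(objects))
  vapply(objects, function(o) as.numeric(o$pixel_area), numeric(1))
}

#' Full per-plot analysis
#'
#' Runs the whole pipeline on one plot: crop to the ROI, segment
#' vegetation, extract noise-filtered plant objects, predict per-object
#' plant counts with a fitted [fit_count_model()] model, and aggregate
#' the plot-level traits.
#'
#' @param image an `rgb_image` of the field (or already-cropped plot).
#' @param model a fitted `count_model`.
#' @param roi optional [plot_roi()]; if `NULL` the whole image is the plot
#'   and `seeds_sown` must be given.
#' @param seeds_sown seeds sown (taken from `roi` when supplied).
#' @param method segmentation method: `"exg_otsu"` (default) or
#'   `"exg_exr_zero"`.
#' @param min_pixels noise-filter threshold in pixels (default 35).
#' @return one-row data.frame: `roi_id`, `n_objects`, `estimated_plants`,
#'   `emergence_rate`, `total_canopy_cm2`, `mean_cover_per_plant_cm2`,
#'   `uniformity_cv` (NA when fewer than 2 objects).
#' @export
summarize_plot <- function(image, model, roi = NULL, seeds_sown = NULL,
                           method = c("exg_otsu", "exg_exr_zero"),
                           min_pixels = 35L) {
  method <- match.arg(method)
  image <- as_rgb_image(image)
  roi_id <- NA
  if (!is.null(roi)) {
    image <- crop_roi(image, roi)
    seeds_sown <- roi$seeds_sown
    roi_id <- roi$roi_id
  }
  if (is.null(seeds_sown))
    stop("'seeds_sown' is required (directly or through the ROI)")
  mask <- segment_field(image, method)
  objects <- detect_plant_objects(mask, min_pixels = min_pixels)
  if (length(objects) == 0L)
    return(data.frame(roi_id = roi_id, n_objects = 0L,
                      estimated_plants = 0L,
                      emergence_rate = 0,
                      total_canopy_cm2 = 0,
                      mean_cover_per_plant_cm2 = NA_real_,
                      uniformity_cv = NA_real_))
  feats <- feature_table(objects, gsd_cm = image$gsd_cm)
  counts <- predict(model, feats)
  est <- sum(counts)
  cm <- canopy_metrics(objects, counts, gsd_cm = image$gsd_cm)
  cv <- if (length(objects) >= 2L)
    uniformity_cv(objects, counts, gsd_cm = image$gsd_cm) else NA_real_
  data.frame(roi_id = roi_id, n_objects = length(objects),
             estimated_plants = est,
             emergence_rate = emergence_rate(est, seeds_sown),
             total_canopy_cm2 = cm$total_canopy_cm2,
             mean_cover_per_plant_cm2 = cm$mean_cover_per_plant_cm2,
             uniformity_cv = cv)
}

#' Segment a field image with a named method
#'
#' Convenience dispatcher pairing each vegetation index with its
#' thresholding rule: `"exg_otsu"` = Excess Green + Otsu (the recommended
#' method), `"exg_exr_zero"` = Excess Green minus Excess Red + fixed zero
#' threshold.
#'
#' @param image an `rgb_image`.
#' @param method method name.
#' @return a `binary_mask`.
#' @export
segment_field <- function(image, method = c("exg_otsu", "exg_exr_zero")) {
  method <- match.arg(method)
  switch(method,
         exg_otsu = segment_vegetation(compute_exg(image), "otsu"),
         exg_exr_zero = segment_vegetation(compute_exg_exr(image), "zero"))
}
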