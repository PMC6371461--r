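#' Specification of a synthetic potato field plot
#'
#' Describes the study conditions a rendered plot emulates: a row-planted
#' plot (by default 6 rows, 270 seeds in total at 75 x 25 cm spacing,
#' the planting geometry of a field subplot), per-seed Bernoulli
#' emergence, quasi-elliptical green canopies over textured brown soil
#' with a low-frequency illumination gradient, and sub-35-pixel green
#' speckle noise. All randomness flows from the single `seed`.
#'
#' @param n_rows number of planted rows.
#' @param seeds_per_plot total seeds sown in the plot.
#' @param row_spacing_cm distance between rows, cm.
#' @param plant_spacing_cm in-row seed spacing, cm (ignored when
#'   `overlap_level` is given).
#' @param overlap_level optional in-row spacing expressed as a multiple of
#'   the mean canopy diameter (< 1 forces overlap, > 1 separates plants).
#' @param emergence_probability probability in \[0, 1\] that a sown seed
#'   produces a plant.
#' @param canopy_radius_mean_cm,canopy_radius_sd_cm canopy radius
#'   distribution (cm); radii are truncated below at 1.5 cm.
#' @param shape_noise 0 for perfect circles; larger values add ellipse
#'   eccentricity, lobes and centre jitter (default 0.2, a moderate,
#'   visibly irregular canopy; together with the radius sd this is
#'   calibrated so overlapping-cluster classes overlap at roughly the
#'   error scale observed in real UAV training data).
#' @param soil_mean,soil_sd soil RGB mean (length-3) and per-channel sd.
#' @param plant_mean,plant_sd canopy RGB mean and sd; green must dominate
#'   red and blue so the Excess Green index is positive in expectation.
#' @param speckle_noise_rate expected green speckles (each < 35 px) per
#'   square metre.
#' @param gsd_cm ground sampling distance, cm per pixel.
#' @param margin_cm bare-soil margin around the planted area.
#' @param seed integer RNG seed.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(n_rows = 6L, seeds_per_plot = 270L,
                       row_spacing_cm = 75, plant_spacing_cm = 25,
                       overlap_level = NULL,
                       emergence_probability = 0.8,
                       canopy_radius_mean_cm = 6, canopy_radius_sd_cm = 0.75,
                       shape_noise = 0.2,
                       soil_mean = c(120, 100, 80), soil_sd = 12,
                       plant_mean = c(60, 130, 55), plant_sd = 8,
                       speckle_noise_rate = 2,
                       gsd_cm = 0.5, margin_cm = 20, seed = 1L) {
  if (emergence_probability < 0 || emergence_probability > 1)
    stop("'emergence_probability' must lie in [0, 1]")
  if (canopy_radius_mean_cm <= 0) stop("canopy radius must be positive")
  if (!(plant_mean[2] > plant_mean[1] && plant_mean[2] > plant_mean[3]))
    stop("plant colour must be green-dominant (G mean above R and B)")
  if (!is.null(overlap_level)) {
    if (overlap_level <= 0) stop("'overlap_level' must be positive")
    plant_spacing_cm <- overlap_level * 2 * canopy_radius_mean_cm
  }
  if (2 * canopy_radius_mean_cm > row_spacing_cm &&
      is.null(overlap_level))
    warning("mean canopy diameter exceeds the row spacing; ",
            "rows will merge into continuous strips")
  structure(list(
    n_rows = as.integer(n_rows), seeds_per_plot = as.integer(seeds_per_plot),
    row_spacing_cm = row_spacing_cm, plant_spacing_cm = plant_spacing_cm,
    emergence_probability = emergence_probability,
    canopy_radius_mean_cm = canopy_radius_mean_cm,
    canopy_radius_sd_cm = canopy_radius_sd_cm,
    shape_noise = shape_noise,
    soil_mean = soil_mean, soil_sd = soil_sd,
    plant_mean = plant_mean, plant_sd = plant_sd,
    speckle_noise_rate = speckle_noise_rate,
    gsd_cm = gsd_cm, margin_cm = margin_cm, seed = as.integer(seed)),
    class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<field_spec> %d rows x %d seeds, %g x %g cm spacing, ",
           "P(emerge) = %.2f, gsd %g cm, seed %d\n"),
    x$n_rows, x$seeds_per_plot, x$row_spacing_cm, x$plant_spacing_cm,
    x$emergence_probability, x$gsd_cm, x$seed))
  invisible(x)
}

#' Render a synthetic field plot with ground truth
#'
#' Draws per-seed emergence, renders each emerged plant as a union of 1-3
#' jittered ellipses (lobed, irregular outlines when `shape_noise > 0`)
#' on textured soil with an illumination gradient, and adds sub-35-pixel
#' green speckles. Fully reproducible from `spec$seed`.
#'
#' @param spec a [field_spec()].
#' @return list with
#'   \describe{
#'     \item{image}{the rendered `rgb_image`;}
#'     \item{truth}{list with `mask` (binary vegetation truth, speckles
#'       excluded), `plants` (data.frame of seed positions, emergence
#'       draws and radii), `true_plants` (emerged count),
#'       `emergence_rate` (percent of seeds), and `object_counts`
#'       (data.frame `label`, `true_count`: true plants per 8-connected
#'       truth-mask component, summing to `true_plants`).}
#'   }
#' @export
generate_field_image <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  g <- spec$gsd_cm
  ppr <- ceiling(spec$seeds_per_plot / spec$n_rows)
  n_seed_pts <- spec$seeds_per_plot
  h <- ceiling((2 * spec$margin_cm + (spec$n_rows - 1) * spec$row_spacing_cm) / g)
  w <- ceiling((2 * spec$margin_cm + (ppr - 1) * spec$plant_spacing_cm) / g)
  with_seed(spec$seed, {
    # seed grid (row-major over rows): positions in px (1-based centres)
    idx <- seq_len(n_seed_pts) - 1L
    ri <- idx %/% ppr; ci <- idx %% ppr
    pr <- (spec$margin_cm + ri * spec$row_spacing_cm) / g + 1
    pc <- (spec$margin_cm + ci * spec$plant_spacing_cm) / g + 1
    emerged <- stats::runif(n_seed_pts) < spec$emergence_probability
    radii <- pmax(1.5, stats::rnorm(n_seed_pts, spec$canopy_radius_mean_cm,
                                    spec$canopy_radius_sd_cm))
    cover <- matrix(0, h, w)
    for (i in which(emerged))
      cover <- render_plant(cover, pr[i], pc[i], radii[i] / g,
                            spec$shape_noise)
    truth <- matrix(as.integer(cover >= 0.5), h, w)
    # speckles: rendered but absent from the truth mask
    area_m2 <- h * w * (g / 100)^2
    n_sp <- stats::rpois(1, spec$speckle_noise_rate * area_m2)
    cover_sp <- matrix(0, h, w)
    if (n_sp > 0) {
      sp_r <- sqrt(stats::runif(n_sp, 3, 25) / pi)   # area 3..25 px < 35
      sp_row <- stats::runif(n_sp, 1, h); sp_col <- stats::runif(n_sp, 1, w)
      for (i in seq_len(n_sp))
        cover_sp <- render_plant(cover_sp, sp_row[i], sp_col[i], sp_r[i], 0.2,
                                 n_lobes = 1L)
    }
    c_all <- pmax(cover, cover_sp)
    # soil texture + canopy blend + illumination gradient
    illum <- 1 + 0.10 * matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE) +
      0.05 * sin(2 * pi * matrix(seq_len(h), h, w) / h)
    px <- render_colours(spec, c_all, illum)
    img <- rgb_image(px, gsd_cm = g)
    # per-component true plant counts (centres always lie in the mask)
    lab <- label_components8(truth)
    obj_counts <- data.frame(label = integer(), true_count = integer())
    if (any(emerged)) {
      cl <- lab[cbind(round(pr[emerged]), round(pc[emerged]))]
      tb <- table(cl)
      obj_counts <- data.frame(label = as.integer(names(tb)),
                               true_count = as.integer(tb))
    }
    plants <- data.frame(row = pr - 1, col = pc - 1,
                         radius_cm = radii, emerged = emerged)
    list(image = img,
         truth = list(
           mask = structure(truth, gsd_cm = g,
                            class = c("binary_mask", "matrix", "array")),
           plants = plants,
           true_plants = sum(emerged),
           emergence_rate = 100 * sum(emerged) / spec$seeds_per_plot,
           object_counts = obj_counts))
  })
}

# accumulate the coverage of one plant (union of jittered ellipses) into
# `cover`; coverage per pixel is estimated on a 2x2 subsample
render_plant <- function(cover, row, col, r_px, shape_noise,
                         n_lobes = NULL) {
  h <- nrow(cover); w <- ncol(cover)
  if (is.null(n_lobes))
    n_lobes <- if (shape_noise > 0) sample(1:3, 1) else 1L
  for (l in seq_len(n_lobes)) {
    cx <- col + stats::rnorm(1, 0, shape_noise * r_px)
    cy <- row + stats::rnorm(1, 0, shape_noise * r_px)
    a <- r_px * stats::runif(1, 1 - shape_noise / 2, 1 + shape_noise / 2)
    b <- r_px * stats::runif(1, 1 - shape_noise / 2, 1 + shape_noise / 2)
    th <- stats::runif(1, 0, pi)
    ext <- ceiling(max(a, b)) + 1L
    rows <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
    cols <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
    if (length(rows) == 0L || length(cols) == 0L) next
    acc <- matrix(0, length(rows), length(cols))
    for (dy in c(-0.25, 0.25)) for (dx in c(-0.25, 0.25)) {
      yy <- outer(rows + dy - cy, rep(1, length(cols)))
      xx <- outer(rep(1, length(rows)), cols + dx - cx)
      u <- xx * cos(th) + yy * sin(th)
      v <- -xx * sin(th) + yy * cos(th)
      acc <- acc + ((u / a)^2 + (v / b)^2 <= 1)
    }
    cover[rows, cols] <- pmax(cover[rows, cols], acc / 4)
  }
  cover
}

#' Generate a labelled training set of overlapping plant clusters
#'
#' Renders small soil tiles each holding a cluster of 1-8 overlapping
#' canopies in a row (the geometry that produces multi-plant connected
#' objects in row-planted fields), segments every tile with the
#' pipeline's own ExG + Otsu route, extracts the plant object, computes
#' the six morphological features and labels the row with the known
#' cluster size. Tiles whose cluster fragments into several objects (or
#' loses a plant to the noise filter) are resampled, up to `max_retries`
#' per tile.
#'
#' @param spec a [field_spec()] supplying colours, canopy size,
#'   calibration and the seed.
#' @param n_objects number of labelled objects (>= 40).
#' @param class_probs probabilities of counts 1..8 (default uniform).
#' @param noise `"moderate"` (the spec's shape and radius noise) or
#'   `"none"` (deterministic circles: classes are perfectly separable).
#' @param cluster_spacing_cm in-cluster plant spacing; below one canopy
#'   diameter so neighbours merge (default 9 cm).
#' @param max_retries resampling cap per tile.
#' @return data.frame with the six feature columns and `count`, plus a
#'   `provenance` attribute describing the generator settings.
#' @export
generate_training_objects <- function(spec, n_objects = 540L,
                                      class_probs = rep(1 / 8, 8),
                                      noise = c("moderate", "none"),
                                      cluster_spacing_cm = 9,
                                      max_retries = 25L) {
  stopifnot(inherits(spec, "field_spec"))
  noise <- match.arg(noise)
  if (n_objects < 40L) stop("need at least 40 training objects")
  if (length(class_probs) != 8L || any(class_probs < 0))
    stop("'class_probs' must be 8 non-negative probabilities")
  g <- spec$gsd_cm
  with_seed(spec$seed + 1L, {
    ks <- sample(1:8, n_objects, replace = TRUE, prob = class_probs)
    rows <- vector("list", n_objects)
    for (i in seq_len(n_objects)) {
      k <- ks[i]
      for (attempt in seq_len(max_retries)) {
        tile <- render_cluster_tile(spec, k, cluster_spacing_cm, noise)
        mask <- segment_field(tile$image, "exg_otsu")
        objs <- detect_plant_objects(mask, min_pixels = 35L)
        if (length(objs) == 0L) next
        # every plant centre must fall in the same single object
        key_cent <- (round(tile$centers[, 1]) - 1) * 1e6 +
          (round(tile$centers[, 2]) - 1)
        hit <- vapply(objs, function(o) {
          key_obj <- o$pixels[, 1] * 1e6 + o$pixels[, 2]
          sum(key_cent %in% key_obj)
        }, numeric(1))
        main <- which.max(hit)
        if (hit[main] == k && sum(hit > 0) == 1L) {
          f <- compute_features(objs[[main]], gsd_cm = g)
          f$count <- k
          rows[[i]] <- f
          break
        }
      }
      if (is.null(rows[[i]]))
        stop("could not render a connected cluster of ", k,
             " plants after ", max_retries, " attempts; reduce ",
             "'cluster_spacing_cm' or the shape noise")
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "provenance") <- sprintf(
      "synthetic clusters: n=%d, noise=%s, spacing=%g cm, seed=%d",
      n_objects, noise, cluster_spacing_cm, spec$seed)
    out
  })
}

render_cluster_tile <- function(spec, k, spacing_cm, noise) {
  g <- spec$gsd_cm
  r_mean <- spec$canopy_radius_mean_cm
  margin <- 2.5 * r_mean
  w <- ceiling((2 * margin + (k - 1) * spacing_cm) / g)
  h <- ceiling(2 * margin / g + 1)
  cy <- h / 2
  cxs <- (margin + (0:(k - 1)) * spacing_cm) / g + 1
  shape_noise <- if (noise == "none") 0 else spec$shape_noise
  cover <- matrix(0, h, w)
  centers <- matrix(0, k, 2)
  for (j in seq_len(k)) {
    r_cm <- if (noise == "none") r_mean else
      pmax(3, stats::rnorm(1, r_mean, spec$canopy_radius_sd_cm))
    jit <- if (noise == "none") c(0, 0) else
      stats::rnorm(2, 0, spec$canopy_radius_sd_cm / g / 2)
    centers[j, ] <- c(cy + jit[1], cxs[j] + jit[2])
    cover <- render_plant(cover, centers[j, 1], centers[j, 2], r_cm / g,
                          shape_noise)
  }
  px <- render_colours(spec, cover, 1)
  list(image = rgb_image(px, gsd_cm = g), centers = centers)
}

# soil and canopy colours: texture is predominantly achromatic (a shared
# per-pixel brightness field, as real illumination/roughness variation
# is), plus small independent per-channel chroma noise, blended by the
# canopy coverage fraction and scaled by the illumination field
render_colours <- function(spec, cover, illum) {
  h <- nrow(cover); w <- ncol(cover)
  bright_soil <- 1 + stats::rnorm(h * w, 0, spec$soil_sd / mean(spec$soil_mean))
  bright_plant <- 1 + stats::rnorm(h * w, 0, spec$plant_sd / mean(spec$plant_mean))
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    soil <- spec$soil_mean[ch] * bright_soil + stats::rnorm(h * w, 0, 3)
    plant <- spec$plant_mean[ch] * bright_plant + stats::rnorm(h * w, 0, 4)
    px[, , ch] <- pmin(255, pmax(0,
      (soil * (1 - cover) + plant * cover) * illum))
  }
  px
}
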