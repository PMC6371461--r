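#' Extract connected plant objects from a vegetation mask
#'
#' Labels 8-connected vegetation components, fills interior holes (canopy
#' gaps at this resolution are illumination artifacts), discards
#' components smaller than `min_pixels` as speckle noise, and returns one
#' plant object per surviving component with its outer contour and
#' minimum-area bounding box. A component may hold several overlapping
#' plants; counting them is [predict_count()]'s job.
#'
#' @param mask a `binary_mask` (or any 0/1 matrix).
#' @param min_pixels minimum component pixel area to keep (default 35;
#'   smaller components are treated as noise).
#' @return a list of `plant_object`s ordered by their top-left-most member
#'   pixel in row-major scan order. Each has fields `object_id`,
#'   `pixel_area`, `pixels` (n x 2, 0-based row/col), `contour` (ordered
#'   0-based boundary coordinates, closed implicitly) and `box` (see
#'   [fit_min_area_box()]). Objects touching the image border are kept.
#' @export
detect_plant_objects <- function(mask, min_pixels = 35L) {
  m <- matrix(as.integer(as.matrix(mask) != 0), nrow(mask), ncol(mask))
  if (sum(m) == 0L) return(list())
  filled <- EBImage::fillHull(m)
  lab <- label_components8(filled)
  nlab <- max(lab)
  idx <- which(lab > 0L)
  by_lab <- split(idx, lab[idx])
  sizes <- lengths(by_lab)
  keep <- names(by_lab)[sizes >= min_pixels]
  if (length(keep) == 0L) return(list())
  contours <- EBImage::ocontour(lab)
  h <- nrow(m)
  objs <- lapply(keep, function(id) {
    lin <- by_lab[[id]]
    r <- ((lin - 1L) %% h) + 1L
    c <- ((lin - 1L) %/% h) + 1L
    ctr <- contours[[as.integer(id)]]        # already 0-based (row, col)
    box <- fit_min_area_box(pixel_corners(ctr))
    structure(list(object_id = NA_integer_,
                   pixel_area = length(lin),
                   pixels = cbind(row = r - 1L, col = c - 1L),
                   contour = ctr,
                   box = box),
              class = "plant_object")
  })
  # deterministic order: first member pixel in row-major scan
  w <- ncol(m)
  key <- vapply(objs, function(o)
    min(o$pixels[, 1] * w + o$pixels[, 2]), numeric(1))
  objs <- objs[order(key)]
  for (i in seq_along(objs)) objs[[i]]$object_id <- i
  objs
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch only diagonally with a union-find pass.
label_components8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n <= 1L) return(matrix(as.integer(lab), nrow(m), ncol(m)))
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]    # \ diagonal neighbours
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1]    # / diagonal neighbours
  pa <- c(a1, a2); pb <- c(b1, b2)
  sel <- pa > 0L & pb > 0L & pa != pb
  parent <- seq_len(n)
  if (any(sel)) {
    ua <- pa[sel]; ub <- pb[sel]
    for (k in seq_along(ua)) {
      ra <- ua[k]; while (parent[ra] != ra) ra <- parent[ra]
      rb <- ub[k]; while (parent[rb] != rb) rb <- parent[rb]
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), function(x) { while (parent[x] != x) x <- parent[x]; x },
                 integer(1))
  relab <- match(root, sort(unique(root)))
  out <- matrix(0L, h, w)
  nz <- lab > 0L
  out[nz] <- relab[lab[nz]]
  out
}

# convex-hull area as a pixel count: number of pixels whose centres lie
# inside (or on) the convex hull of the boundary pixel centres — the
# rasterised-hull convention, so a convex solid shape has solidity 1 and
# solidity never exceeds 1
convex_pixel_count <- function(contour) {
  pts <- unique(contour)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  if (length(hull) < 3L) return(nrow(pts))   # line: hull degenerates
  hr <- pts[hull, 1]; hc <- pts[hull, 2]
  n <- length(hull)
  nxt <- c(2:n, 1L)
  orient <- sign(sum(hc * hr[nxt] - hc[nxt] * hr))  # polygon winding
  rows <- min(hr):max(hr); cols <- min(hc):max(hc)
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- matrix(TRUE, length(rows), length(cols))
  for (i in seq_len(n)) {
    j <- nxt[i]
    cross <- (hc[j] - hc[i]) * (rr - hr[i]) - (hr[j] - hr[i]) * (cc - hc[i])
    inside <- inside & (orient * cross >= -1e-9)
  }
  sum(inside)
}

# corner points (r +/- 0.5, c +/- 0.5) of boundary pixels, 0-based coords
pixel_corners <- function(contour) {
  r <- contour[, 1]; c <- contour[, 2]
  cbind(rep(r, 4) + rep(c(-0.5, -0.5, 0.5, 0.5), each = length(r)),
        rep(c, 4) + rep(c(-0.5, 0.5, -0.5, 0.5), each = length(r)))
}

#' Minimum-area rotated bounding box
#'
#' Fits the smallest-area rectangle, at any rotation, enclosing a point
#' set. Uses the rotating-calipers theorem: the optimal rectangle has one
#' side collinear with a convex-hull edge, so only hull-edge orientations
#' need checking. For a `plant_object` the enclosed points are the corner
#' points of its boundary pixels, so the box encloses the full pixel
#' squares (an axis-aligned solid 20 x 8 pixel rectangle yields exactly a
#' 20 x 8 box).
#'
#' @param x a `plant_object` or an n x 2 numeric matrix of (row, col)
#'   points with at least 3 non-collinear points.
#' @return a list with `center` (row, col), `width_px` (extent along
#'   `angle`), `height_px` (perpendicular extent) and `angle` in degrees
#'   within \[0, 90).
#' @export
fit_min_area_box <- function(x) {
  pts <- if (inherits(x, "plant_object")) pixel_corners(x$contour)
         else as.matrix(x)
  if (!is.numeric(pts) || ncol(pts) != 2L)
    stop("expected a plant_object or an n x 2 coordinate matrix")
  pts <- unique(pts)
  if (nrow(pts) < 3L)
    stop("degenerate geometry: fewer than 3 distinct points")
  hull <- grDevices::chull(pts[, 2], pts[, 1])   # (x = col, y = row)
  hp <- pts[hull, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3L) stop("degenerate geometry: points are collinear")
  y <- hp[, 1]; xx <- hp[, 2]
  # collinearity check via cross products
  if (all(abs((xx[-1][-1] - xx[1]) * (y[2] - y[1]) -
              (y[-1][-1] - y[1]) * (xx[2] - xx[1])) < 1e-9))
    stop("degenerate geometry: points are collinear")
  best <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    dx <- xx[j] - xx[i]; dy <- y[j] - y[i]
    len <- sqrt(dx^2 + dy^2)
    if (len < 1e-12) next
    ct <- dx / len; st <- dy / len
    u <- xx * ct + y * st
    v <- -xx * st + y * ct
    wu <- max(u) - min(u); wv <- max(v) - min(v)
    area <- wu * wv
    if (is.null(best) || area < best$area - 1e-12) {
      cu <- (max(u) + min(u)) / 2; cv <- (max(v) + min(v)) / 2
      best <- list(area = area, wu = wu, wv = wv,
                   cx = cu * ct - cv * st, cy = cu * st + cv * ct,
                   theta = atan2(st, ct))
    }
  }
  th <- best$theta %% pi
  wu <- best$wu; wv <- best$wv
  if (th >= pi / 2) { th <- th - pi / 2; tmp <- wu; wu <- wv; wv <- tmp }
  list(center = c(row = best$cy, col = best$cx),
       width_px = wu, height_px = wv, angle = th * 180 / pi)
}

#' Morphological features of a plant object
#'
#' Computes the six features of the minimum-area bounding box and contour
#' used to predict plant number, in physical units given the ground
#' sampling distance: box length (long side, cm), length-width ratio,
#' canopy area (cm^2), outer-contour perimeter (cm), convex-hull area
#' (cm^2), and solidity (canopy area / convex-hull area). Convex area is
#' measured as a pixel count over the rasterised hull (pixels whose
#' centres fall inside the hull of the boundary pixel centres), so a
#' convex solid shape has solidity 1 (up to discretisation) and solidity
#' never exceeds 1.
#'
#' @param object a `plant_object` from [detect_plant_objects()].
#' @param gsd_cm ground sampling distance, cm per pixel.
#' @return a one-row `data.frame` with columns `length_cm`,
#'   `length_width_ratio`, `area_cm2`, `perimeter_cm`, `convex_area_cm2`,
#'   `solidity`.
#' @export
compute_features <- function(object, gsd_cm) {
  stopifnot(inherits(object, "plant_object"),
            is.numeric(gsd_cm), length(gsd_cm) == 1L, gsd_cm > 0)
  box <- object$box
  sides <- c(box$width_px, box$height_px)
  if (min(sides) <= 0)
    stop("degenerate geometry: bounding box has zero width")
  ctr <- object$contour
  n <- nrow(ctr)
  per_px <- if (n < 2L) 0 else {
    nxt <- c(2:n, 1L)
    sum(sqrt((ctr[nxt, 1] - ctr[, 1])^2 + (ctr[nxt, 2] - ctr[, 2])^2))
  }
  area <- object$pixel_area * gsd_cm^2
  convex <- convex_pixel_count(ctr) * gsd_cm^2
  data.frame(length_cm = max(sides) * gsd_cm,
             length_width_ratio = max(sides) / min(sides),
             area_cm2 = area,
             perimeter_cm = per_px * gsd_cm,
             convex_area_cm2 = convex,
             solidity = area / convex)
}

#' Feature table for a set of plant objects
#'
#' @param objects list of `plant_object`s.
#' @param gsd_cm ground sampling distance, cm per pixel.
#' @return a `data.frame` with `object_id`, `pixel_area` and the six
#'   feature columns of [compute_features()], one row per object.
#' @export
feature_table <- function(objects, gsd_cm) {
  if (length(objects) == 0L)
    return(data.frame(object_id = integer(), pixel_area = integer(),
                      length_cm = numeric(), length_width_ratio = numeric(),
                      area_cm2 = numeric(), perimeter_cm = numeric(),
                      convex_area_cm2 = numeric(), solidity = numeric()))
  feats <- do.call(rbind, lapply(objects, compute_features, gsd_cm = gsd_cm))
  cbind(data.frame(object_id = vapply(objects, `[[`, 1L, "object_id"),
                   pixel_area = vapply(objects, `[[`, 1L, "pixel_area")),
        feats)
}

#' @export
print.plant_object <- function(x, ...) {
  cat(sprintf(
    "<plant_object> id %s, %d px, box %.1f x %.1f px at %.1f deg\n",
    x$object_id, x$pixel_area, x$box$width_px, x$box$height_px, x$box$angle))
  invisible(x)
}

#' Write an annotated overlay PNG
#'
#' Draws each object's minimum-area bounding box (red) onto the RGB image
#' and writes the result as PNG; predicted counts, if given, are listed in
#' a companion CSV (`<path>.counts.csv`) keyed by object id.
#'
#' @param image an `rgb_image`.
#' @param objects list of `plant_object`s.
#' @param path output PNG path.
#' @param counts optional integer vector of predicted plant counts,
#'   parallel to `objects`.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, objects, path, counts = NULL) {
  image <- as_rgb_image(image)
  arr <- image$pixels / 255
  h <- dim(arr)[1]; w <- dim(arr)[2]
  for (o in objects) {
    b <- o$box
    th <- b$angle * pi / 180
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))  # (col, row) axes
    cc <- b$center[["col"]]; cr <- b$center[["row"]]
    half <- list(u * b$width_px / 2, v * b$height_px / 2)
    corn <- rbind(c(cc, cr) + half[[1]] + half[[2]],
                  c(cc, cr) + half[[1]] - half[[2]],
                  c(cc, cr) - half[[1]] - half[[2]],
                  c(cc, cr) - half[[1]] + half[[2]])
    for (e in 1:4) {
      p1 <- corn[e, ]; p2 <- corn[if (e == 4) 1 else e + 1, ]
      npt <- max(2L, ceiling(sqrt(sum((p2 - p1)^2)) * 2))
      cs <- round(seq(p1[1], p2[1], length.out = npt)) + 1L
      rs <- round(seq(p1[2], p2[2], length.out = npt)) + 1L
      ok <- rs >= 1 & rs <= h & cs >= 1 & cs <= w
      arr[cbind(rs[ok], cs[ok], 1L)] <- 1
      arr[cbind(rs[ok], cs[ok], 2L)] <- 0
      arr[cbind(rs[ok], cs[ok], 3L)] <- 0
    }
  }
  png::writePNG(arr, path)
  if (!is.null(counts)) {
    utils::write.csv(
      data.frame(object_id = vapply(objects, `[[`, 1L, "object_id"),
                 count = counts),
      paste0(path, ".counts.csv"), row.names = FALSE)
  }
  invisible(path)
}
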