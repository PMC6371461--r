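test_that("noise filter keeps 35-pixel components and drops smaller ones", {
  # a 34-pixel blob (2 x 17) and a 40-pixel blob (4 x 10), well separated
  m <- blob_mask(30, 40, list(c(2, 2, 2, 17), c(20, 5, 4, 10)))
  objs <- detect_plant_objects(m)
  expect_length(objs, 1L)
  expect_equal(objs[[1]]$pixel_area, 40L)
})

test_that("empty mask yields an empty object list", {
  expect_identical(detect_plant_objects(matrix(0L, 10, 10)), list())
})

test_that("well-separated blobs are found with exact areas, in scan order", {
  m <- blob_mask(60, 60, list(c(40, 40, 10, 10), c(5, 30, 10, 10),
                              c(20, 3, 10, 10)))
  objs <- detect_plant_objects(m)
  expect_length(objs, 3L)
  expect_equal(vapply(objs, `[[`, 1L, "pixel_area"), c(100L, 100L, 100L))
  # row-major order of the top-left-most member pixel
  first_rows <- vapply(objs, function(o) min(o$pixels[, 1]), numeric(1))
  expect_equal(first_rows, c(4, 19, 39))
  expect_equal(vapply(objs, `[[`, 1L, "object_id"), 1:3)
})

test_that("components are 8-connected: diagonal touch joins objects", {
  m <- matrix(0L, 20, 20)
  m[2:8, 2:8] <- 1L
  m[9:15, 9:15] <- 1L   # touches only at the corner
  objs <- detect_plant_objects(m, min_pixels = 10)
  expect_length(objs, 1L)
  expect_equal(objs[[1]]$pixel_area, 2L * 49L)
})

test_that("object count is invariant to translation and speckle noise", {
  base <- list(c(5, 5, 8, 6), c(5, 30, 6, 8), c(25, 10, 7, 7))
  m <- blob_mask(50, 50, base)
  shifted <- blob_mask(50, 50, lapply(base, function(b) b + c(7, 4, 0, 0)))
  set.seed(21)
  noisy <- m
  for (i in 1:10) {  # sub-35-pixel speckles away from the blobs
    r <- sample(40:48, 1); c <- sample(2:45, 1)
    noisy[r:(r + 1), c:(c + 2)] <- 1L
  }
  n0 <- length(detect_plant_objects(m))
  expect_identical(length(detect_plant_objects(shifted)), n0)
  expect_identical(length(detect_plant_objects(noisy)), n0)
})

test_that("interior holes are filled for area and contour", {
  m <- blob_mask(20, 20, list(c(3, 3, 10, 10)))
  holed <- m
  holed[6:8, 6:8] <- 0L
  a <- detect_plant_objects(m)[[1]]
  b <- detect_plant_objects(holed)[[1]]
  expect_equal(b$pixel_area, a$pixel_area)
  expect_equal(b$contour, a$contour)
})

test_that("min-area box of an axis-aligned rectangle is the rectangle", {
  m <- blob_mask(30, 40, list(c(5, 5, 8, 20)))
  obj <- detect_plant_objects(m)[[1]]
  sides <- sort(c(obj$box$width_px, obj$box$height_px))
  expect_equal(sides, c(8, 20), tolerance = 1e-8)
  expect_equal(obj$box$width_px * obj$box$height_px, 160, tolerance = 1e-8)
})

test_that("min-area box follows a rotated rectangle", {
  # rasterise a 20 x 8 rectangle rotated 45 degrees
  th <- pi / 4
  rr <- matrix(seq_len(60), 60, 60)
  cc <- matrix(seq_len(60), 60, 60, byrow = TRUE)
  u <- (cc - 30) * cos(th) + (rr - 30) * sin(th)
  v <- -(cc - 30) * sin(th) + (rr - 30) * cos(th)
  m <- matrix(as.integer(abs(u) <= 10 & abs(v) <= 4), 60, 60)
  obj <- detect_plant_objects(m)[[1]]
  area <- obj$box$width_px * obj$box$height_px
  expect_equal(area, 160, tolerance = 0.15)       # +/- 1 px rasterisation
  expect_equal(obj$box$angle, 45, tolerance = 3)
})

test_that("min-area box of a disc is a square of the diameter", {
  m <- disc_mask(40, 40, 20, 20, 10)
  obj <- detect_plant_objects(m)[[1]]
  expect_equal(obj$box$width_px, 20, tolerance = 0.1)
  expect_equal(obj$box$height_px, 20, tolerance = 0.1)
})

test_that("min-area box matches a dense rotation sweep on random point sets", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    pts <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    box <- fit_min_area_box(pts)
    impl_area <- box$width_px * box$height_px
    sweep_area <- sweep_min_box_area(pts)
    expect_lte(impl_area, sweep_area + 1e-9)
    expect_lt(abs(impl_area - sweep_area) / sweep_area, 0.005)
  }
})

test_that("degenerate geometry is rejected", {
  expect_error(fit_min_area_box(cbind(1:5, 1:5)), "collinear|degenerate")
  expect_error(fit_min_area_box(cbind(1, 1)), "degenerate")
})

test_that("features of a 20 x 8 rectangle at gsd 0.5 match hand arithmetic", {
  m <- blob_mask(30, 40, list(c(5, 5, 8, 20)))
  obj <- detect_plant_objects(m)[[1]]
  f <- compute_features(obj, gsd_cm = 0.5)
  expect_equal(f$length_cm, 10)               # 20 px * 0.5
  expect_equal(f$length_width_ratio, 2.5)     # 20 / 8
  expect_equal(f$area_cm2, 40)                # 160 px * 0.25
  expect_equal(f$convex_area_cm2, 40)         # convex: hull = rectangle
  expect_equal(f$solidity, 1)
})

test_that("solidity is 1 for convex shapes and below 1 for concave ones", {
  disc <- detect_plant_objects(disc_mask(40, 40, 20, 20, 12))[[1]]
  f <- compute_features(disc, gsd_cm = 1)
  expect_equal(f$solidity, 1, tolerance = 0.02)
  u <- blob_mask(40, 40, list(c(5, 5, 25, 6), c(5, 25, 25, 6),
                              c(27, 5, 5, 26)))   # U shape, 8-connected
  obj <- detect_plant_objects(u)[[1]]
  expect_lt(compute_features(obj, gsd_cm = 1)$solidity, 0.8)
})

test_that("feature scaling follows the ground sampling distance", {
  m <- blob_mask(40, 40, list(c(5, 8, 11, 23)))
  obj <- detect_plant_objects(m)[[1]]
  f1 <- compute_features(obj, gsd_cm = 0.5)
  f2 <- compute_features(obj, gsd_cm = 1.0)
  expect_equal(f2$length_cm, 2 * f1$length_cm)
  expect_equal(f2$perimeter_cm, 2 * f1$perimeter_cm)
  expect_equal(f2$area_cm2, 4 * f1$area_cm2)
  expect_equal(f2$convex_area_cm2, 4 * f1$convex_area_cm2)
  expect_equal(f2$length_width_ratio, f1$length_width_ratio)
  expect_equal(f2$solidity, f1$solidity)
})

test_that("every detected object satisfies the solidity and hull invariants", {
  fld <- generate_field_image(field_spec(n_rows = 2, seeds_per_plot = 30,
                                         seed = 13))
  objs <- detect_plant_objects(segment_field(fld$image, "exg_otsu"))
  expect_gt(length(objs), 5)
  ft <- feature_table(objs, gsd_cm = 0.5)
  expect_true(all(ft$area_cm2 <= ft$convex_area_cm2 + 1e-9))
  expect_true(all(ft$solidity > 0 & ft$solidity <= 1 + 1e-9))
  expect_true(all(ft$length_width_ratio >= 1))
  expect_true(all(ft$length_cm > 0))
})
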