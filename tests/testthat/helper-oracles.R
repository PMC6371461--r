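# Independent oracles and fixture builders shared across the suite.

# Brute-force Otsu: assign pixels to 256 bins over [min, max], try every
# cut, compute the between-class variance directly from the class split,
# lowest cut wins ties. Returns the 0/1 class assignment (1 = high class).
brute_force_otsu_classes <- function(v, n_bins = 256L) {
  mn <- min(v); mx <- max(v)
  bw <- (mx - mn) / n_bins
  bin <- pmin(floor((v - mn) / bw), n_bins - 1L)
  best_var <- -Inf; best_t <- NA
  for (t in 0:(n_bins - 2L)) {
    lo <- v[bin <= t]; hi <- v[bin > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    # between-class variance in bin space, as the implementation optimises
    blo <- bin[bin <= t]; bhi <- bin[bin > t]
    s <- length(lo) * length(hi) / length(v)^2 * (mean(blo) - mean(bhi))^2
    if (s > best_var + 1e-12) { best_var <- s; best_t <- t }
  }
  as.integer(bin > best_t)
}

# Dense rotation sweep for the minimum-area bounding box: axis-aligned
# box area of the points rotated through a fine grid of angles.
sweep_min_box_area <- function(pts, step_deg = 0.2) {
  best <- Inf
  for (th in seq(0, 90 - step_deg, by = step_deg) * pi / 180) {
    u <- pts[, 2] * cos(th) + pts[, 1] * sin(th)
    v <- -pts[, 2] * sin(th) + pts[, 1] * cos(th)
    a <- (max(u) - min(u)) * (max(v) - min(v))
    if (a < best) best <- a
  }
  best
}

# binary mask with rectangular blobs; blobs = list of c(r0, c0, h, w), 1-based
blob_mask <- function(h, w, blobs) {
  m <- matrix(0L, h, w)
  for (b in blobs) m[b[1]:(b[1] + b[3] - 1), b[2]:(b[2] + b[4] - 1)] <- 1L
  m
}

# solid disc mask
disc_mask <- function(h, w, cr, cc, radius) {
  rr <- matrix(seq_len(h), h, w); cc2 <- matrix(seq_len(w), h, w, byrow = TRUE)
  matrix(as.integer((rr - cr)^2 + (cc2 - cc)^2 <= radius^2), h, w)
}

# cached moderate-noise training set (generation is the slow step; unit
# tests share one instance, acceptance tests build their own at n = 540)
shared_training_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_training_objects(field_spec(seed = 404),
                                          n_objects = 240)
    cache
  }
})

# perfectly separable labelled set: area strictly proportional to count
separable_training_set <- function(n = 80, seed = 1) {
  set.seed(seed)
  k <- sample(1:8, n, replace = TRUE)
  data.frame(length_cm = 10 * k, length_width_ratio = 1 + 0 * k,
             area_cm2 = 50 * k, perimeter_cm = 20 * k,
             convex_area_cm2 = 55 * k, solidity = rep(0.9, n),
             count = k)
}
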