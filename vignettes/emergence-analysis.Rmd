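---
title: "Estimating crop emergence from RGB field imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating crop emergence from RGB field imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emergekit)
```

## The problem

Counting emerged plants in a row crop such as potato is the first
quantitative assessment of a growing season: the emergence rate (plants
per seeds sown), the canopy cover per plant, and the uniformity of early
growth all predict later performance and respond to cultivar and
fertiliser treatments. Manual counting is slow and subjective; a
low-altitude RGB survey at a ground sampling distance (GSD) of roughly
0.5 cm per pixel makes the assessment automatic, but raises three image
analysis problems that this package solves in sequence:

1. **Segmentation** — separate green canopy from soil.
2. **Object counting** — emerged plants overlap, so a connected green
   region ("plant object") may hold several plants that cannot be
   separated geometrically; the number of plants per object is instead
   *predicted* from the object's shape.
3. **Aggregation** — turn per-object counts and areas into plot-level
   traits.

## Segmentation model

An RGB pixel is mapped to a vegetation-index greyscale. Two indices are
provided, with their conventional thresholding rules:

* **ExG** (Excess Green), $\mathrm{ExG} = 2G - R - B$, thresholded
  automatically by Otsu's between-class-variance criterion
  (`segment_field(img, "exg_otsu")`).
* **ExG−ExR** (Excess Green minus Excess Red),
  $3G - 2.4R - B$, thresholded at the fixed value 0, relying on the
  index mapping plant pixels to positive values
  (`segment_field(img, "exg_exr_zero")`).

ExG is invariant to additive brightness offsets ($2c - c - c = 0$) and
achromatic texture (soil roughness varies brightness, not hue, and
$R=G=B$ noise cancels exactly), which is why it pairs well with an
adaptive threshold. Because a vegetation index is a signed real rather
than an 8-bit count, Otsu's method runs on a 256-bin histogram over the
observed $[\min,\max]$ range; ties between cuts take the lowest bin, and
the returned threshold is the midpoint between the nearest observed
values on either side of the chosen cut, so `value > threshold`
reproduces the bin classification exactly. A constant image raises an
explicit degenerate-histogram error. No smoothing or denoising is
applied before thresholding. When plots are analysed through ROIs, the
threshold is computed independently per cropped ROI, not globally, so
illumination differences between plots do not bias each other.

Segmentation quality against a reference mask is scored with the
quality factor $Q = |P \wedge B| / |P \vee B|$ (intersection over
union); $Q = 1$ only for a perfect, non-empty match, and $Q$ over two
empty masks is an error (0/0), not a sentinel value.

```{r q-demo}
fld <- generate_field_image(field_spec(n_rows = 2, seeds_per_plot = 24,
                                       seed = 1))
mask <- segment_field(fld$image, "exg_otsu")
quality_factor(mask, fld$truth$mask)
```

## Plant objects and their features

Vegetation components are labelled with 8-connectivity (thin diagonal
stems stay connected), interior holes are filled (canopy gaps at 0.5 cm
GSD are illumination artifacts, so area and perimeter describe the
outer outline), and components under 35 pixels are discarded as noise —
the threshold is exposed as `min_pixels` and interpreted as component
pixel *area*. Objects touching the ROI border are kept; discarding them
would bias emergence downward. Object order is deterministic (top-left
member pixel, row-major), and coordinates are 0-based (row, col).

Each object gets a minimum-area rotated bounding box, computed by the
rotating-calipers theorem over the convex hull of the boundary pixels'
*corner* points, so the box encloses whole pixel squares: an
axis-aligned solid 20 × 8 px rectangle yields exactly a 20 × 8 box. Box
angles are reported in degrees in [0, 90).

Six morphological features are computed in physical units from the GSD:

| feature | definition |
|---|---|
| `length_cm` | long side of the box |
| `length_width_ratio` | long / short side (≥ 1) |
| `area_cm2` | member pixel count × GSD² |
| `perimeter_cm` | polygonal arc length of the traced outer contour (diagonal steps √2) |
| `convex_area_cm2` | rasterised convex hull pixel count × GSD² |
| `solidity` | area / convex area, in (0, 1] |

Convex area uses the rasterised-hull convention (pixels whose centres
lie inside the hull of the boundary pixel centres): this makes solidity
exactly 1 for solid rectangles, ≈ 1 for discs, and guarantees
solidity ≤ 1, because every member pixel's centre is inside the hull.
Doubling the GSD doubles lengths and quadruples areas while leaving the
two ratios unchanged.

## The count model

`fit_count_model()` trains a Random Forest classifier mapping the six
features to the number of plants in an object, restricted to counts
1–8; larger clusters are an explicit error rather than a silent clamp,
because no training evidence exists beyond 8. Defaults follow standard
practice: 100 trees (the out-of-bag error is flat beyond roughly 75
trees), 2 features per split (≈ √6), unlimited depth, bootstrap equal
to the training size, no class reweighting. The labelled set is split
80/20 stratified by class — with eight classes a small unstratified
holdout can miss rare counts entirely. Prediction is the majority vote
over trees; ties resolve to the *smaller* count, a conservative choice
against the overestimation tendency for mid-sized objects. All
randomness derives from the explicit `seed` argument, and fitting
restores the caller's RNG state.

Variable importance is the permutation measure: the mean increase in
out-of-bag error when one feature's values are permuted, averaged over
trees, reported raw (unnormalised) and floored at zero. On row-planted
data the box length dominates, since clusters grow along the row, and
solidity ranks last — connected canopies are all similarly solid.

## Plot-level traits

For a plot with $n$ objects carrying predicted counts $k_i$ and areas
$a_i$ (cm²):

* **emergence rate** $= 100 \cdot \sum_i k_i / \text{seeds sown}$, with
  the seeds-sown denominator taken from the plot configuration (e.g.
  270 or 210 per plot), never inferred from imagery;
* **mean canopy cover per plant** $= \sum_i a_i / \sum_i k_i$;
* **uniformity CV** $= 100 \cdot \mathrm{sd}(a_i/k_i) /
  \mathrm{mean}(a_i/k_i)$, using the sample (n−1) standard deviation
  over the per-object cover-per-plant values, unweighted by count.

The CV is invariant to the GSD and to uniform area scaling. Plants
removed by the 35-pixel filter contribute to neither counts nor canopy
— a known downward bias for very small seedlings at this resolution.

## What the synthetic generator emulates

`field_spec()` + `generate_field_image()` render a row-planted plot
with known ground truth. Defaults describe one field subplot: 6 rows,
270 seeds at 75 × 25 cm spacing, GSD 0.5 cm. Each seed emerges with
probability `emergence_probability`; an emerged plant is a union of 1–3
jittered ellipses (canopies of small plants are lobed and irregular,
which is exactly what defeats the length–width ratio as a counting
feature), with radius ~ N(6, 0.75) cm. Soil is rendered as a brown mean
under a shared per-pixel brightness field plus small chroma noise —
soil texture in real imagery is achromatic, so it cancels in ExG — with
a low-frequency illumination gradient across the plot, and green
speckles under 35 px are sprinkled at `speckle_noise_rate` per m²
(present in the rendered image, absent from the truth mask). The
shape-noise and radius-sd defaults are calibrated so that
overlapping-cluster classes overlap at about the error scale observed
in real UAV training data (out-of-bag error around 4–6%).

Ground truth records each plant, the vegetation mask (coverage ≥ 0.5),
and the true plant count of every connected mask component; these
conserve the plot total exactly. `generate_training_objects()` renders
labelled clusters of 1–8 plants at 9 cm in-cluster spacing, segments
them with the pipeline's own ExG + Otsu route, and resamples any tile
whose cluster fragments; the `"none"` noise preset produces
deterministic, perfectly separable classes used to validate the
classifier's ceiling.

What the generator does **not** emulate: weeds, senescent or purple
foliage, cast shadows, perspective and stitching artifacts, and
radiometric miscalibration. Passing the recovery experiments therefore
shows the pipeline is internally consistent and correctly implemented,
not that it transfers to arbitrary field conditions.

## Validation experiments

The test suite runs scaled recovery experiments chosen to finish in
minutes on one CPU:

* a 540-object training set (counts 1–8, moderate noise, fixed seed)
  must reach ≥ 90% holdout accuracy, and 100% on the noiseless preset;
* across 30 rendered plots (3 rows × 90 seeds) spanning 15–90% true
  emergence, estimated vs. true emergence must reach r² ≥ 0.9 — in the
  run recorded during development it reached r² ≈ 0.997 with RMSE
  ≈ 1.8 percentage points and slope ≈ 1.01;
* with dark-brown soil, mean Q of ExG + Otsu must exceed that of
  zero-threshold ExG−ExR: the darker soil narrows the ExG−ExR margin,
  so the fixed zero threshold mislabels canopy-edge mixture pixels that
  the adaptive cut assigns correctly. This is asserted as a direction,
  not a magnitude.

Geometry and thresholding are checked against independent oracles: an
exhaustive between-class-variance search for Otsu and a dense rotation
sweep for the minimum-area box.

```{r recovery, eval = FALSE}
train <- generate_training_objects(field_spec(seed = 2024), 540)
model <- fit_count_model(train[, feature_names()], train$count,
                         seed = 2024)
model
summary(model)
```

## Numerical and degenerate-input choices

* Otsu on a constant image, Q on two empty masks, regression on a
  constant reference, clusters beyond 8 plants, and ROIs that miss the
  image all raise informative errors rather than returning sentinels.
* Collinear point sets have no minimum-area box and raise a
  degenerate-geometry error; single-pixel and line components never
  reach that path because boxes are fitted to pixel corners.
* `regress_paired()` reports RMSE against the 1:1 line (root mean
  square of raw paired differences), not residual RMSE — the two
  coincide only when the fit is the identity.
* Model artifacts saved with `save_count_model()` carry a JSON sidecar
  (tree count, seed, feature order, MD5) for provenance.
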