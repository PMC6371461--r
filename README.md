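# emergekit

Estimates crop emergence from high-resolution RGB field imagery of
row-planted crops, developed for potato at the emergence stage. Given an
orthomosaic-style image at a known ground sampling distance (GSD, ~0.5
cm/px for a low-altitude UAV survey) and per-plot seed counts, the
package reports three plot-level traits used to compare cultivars and
fertiliser treatments:

* **emergence rate** — predicted plants as a percentage of seeds sown;
* **mean canopy cover per plant** (cm²);
* **emergence uniformity** — the coefficient of variation of per-object
  canopy cover per plant (lower = more uniform).

## Method

1. **Segmentation.** The RGB image is transformed to a vegetation index
   — Excess Green, ExG = 2G − R − B, binarised by Otsu's
   between-class-variance threshold, or ExG − ExR = 3G − 2.4R − B,
   binarised at the fixed value 0 — producing a canopy/soil mask.
   Segmentation quality against a reference mask is scored by the
   intersection-over-union quality factor
   Q = |P ∧ B| / |P ∨ B| (Q = 1 for a perfect match).
2. **Plant objects.** 8-connected vegetation components under 35 px are
   discarded as noise; each surviving component gets a minimum-area
   rotated bounding box and six morphological features in physical
   units: box length, length–width ratio, canopy area, contour
   perimeter, convex-hull area, and solidity.
3. **Counting.** Overlapping plants are not split geometrically;
   instead a Random Forest classifier (100 trees, 80/20 stratified
   split, tie votes to the smaller class) predicts the number of plants
   (1–8) in each object from its features. Out-of-bag error, holdout
   accuracy, permutation variable importance and confusion matrices are
   reported.
4. **Aggregation.** Per-ROI plant counts, canopy totals and the
   uniformity CV; estimated-vs-reference agreement via OLS r² and
   1:1-line RMSE.

A synthetic field generator (`field_spec()`, `generate_field_image()`,
`generate_training_objects()`) renders row-planted plots and labelled
plant clusters with exact ground truth, so the whole pipeline is
testable without UAV data.

## Worked example

```r
library(emergekit)

# labelled training clusters (counts 1-8) rendered and segmented by the
# pipeline itself, then a count model
train <- generate_training_objects(field_spec(seed = 2024), n_objects = 540)
model <- fit_count_model(train[, feature_names()], train$count, seed = 2024)
model
#> <count_model> Random Forest, 100 trees, classes 1-8
#>   trained on 431 objects (holdout 109): holdout accuracy 0.954, OOB error 0.049

sort(variable_importance(model), decreasing = TRUE)
#>          length_cm       perimeter_cm length_width_ratio    convex_area_cm2
#>             0.4269             0.3100             0.1882             0.1411
#>           solidity           area_cm2
#>             0.1260             0.0820

# a synthetic 3-row plot, 90 seeds, 60% emergence probability
fld <- generate_field_image(field_spec(n_rows = 3, seeds_per_plot = 90,
                                       emergence_probability = 0.6, seed = 42))
fld$truth$true_plants        # 50 plants truly emerged (55.6 %)

summarize_plot(fld$image, model, seeds_sown = 90)
#>   roi_id n_objects estimated_plants emergence_rate total_canopy_cm2
#> 1     NA        50               51          56.67             6454
#>   mean_cover_per_plant_cm2 uniformity_cv
#> 1                    126.6         31.09

quality_factor(segment_field(fld$image, "exg_otsu"), fld$truth$mask)
#> 0.974
```

The model recovers 51 of the 50 truly emerged plants (56.7% vs 55.6%
emergence); box length dominates the importance ranking because plants
are set out in rows, and solidity carries little signal. Across 30 such
plots spanning 15–90% emergence, estimated vs. true emergence reaches
r² ≈ 0.997 (see the test suite).

A thin command-line front end is installed at
`inst/scripts/emergekit` (`synth-field`, `synth-train`, `train`, `run`,
`evaluate-counts`, `evaluate-segmentation`); see its header for usage.

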