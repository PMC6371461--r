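Package: emergekit
Title: Crop Emergence Estimation from UAV RGB Field Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates crop emergence rate, canopy cover and emergence
    uniformity of row-planted crops (developed for potato) from
    high-resolution RGB field imagery. Vegetation is separated from soil by
    colour-index transforms (Excess Green, Excess Green minus Excess Red)
    with automatic Otsu or fixed zero thresholding; connected plant objects
    are extracted, filtered for speckle noise, and described by six
    morphological features of their minimum-area bounding boxes; a Random
    Forest classifier predicts the number of overlapping plants in each
    object. Includes a synthetic field-image generator with known ground
    truth for end-to-end validation, segmentation-quality scoring
    (intersection-over-union quality factor), and estimated-versus-reference
    regression diagnostics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    randomForest,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0), tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
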