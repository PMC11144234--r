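Package: fireveg
Title: Post-Fire Vegetation Change Detection, Trend Analysis, and Recovery Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for assessing wildfire impact on vegetation from
    satellite vegetation-index rasters. Provides five-class NDVI mapping,
    bi-temporal change detection via a sparse autoencoder and deep embedded
    clustering, per-pixel Sen's-slope trend analysis of annual EVI composites
    with greening/browning fractions, a stacking ensemble predicting regrowth
    possibility from soil attributes, and an adversarially trained
    encoder-decoder network (with self-attention and a PatchGAN critic) that
    generates vegetation recovery maps, together with regression metrics and a
    homoscedasticity diagnostic. Includes seeded synthetic-scene generators
    with known ground truth so every stage is testable without satellite
    downloads, and a command-line interface tying the stages into a workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest
Config/testthat/edition: 3
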