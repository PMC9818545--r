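Package: histopatch
Title: Patch-Based Classification of H&E Breast Histopathology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-stage classification of hematoxylin-and-eosin breast
    histology images. Images are tiled into overlapping 512x512 patches that
    inherit the image label, stain-normalized to a template with the Macenko
    method, embedded through a pluggable convolutional backbone, and scored by
    a trainable fine-tuning head whose global-average-pooling output provides
    512-dimensional patch features. Patch features are classified by an
    ensemble of five classical classifiers (k-nearest neighbours, support
    vector machine, random forest, adaptive boosting, gradient-boosted trees)
    fused by average, product or maximum rules, and patch predictions are
    aggregated to image-level two-class (cancerous vs non-cancerous) and
    four-class (normal, benign, in situ, invasive) predictions through a
    two-stage frequency-array neural aggregator. Includes a synthetic H&E
    fixture generator based on a two-stain Beer-Lambert mixture so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    yaml,
    caret,
    e1071,
    randomForest,
    xgboost,
    rpart
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
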