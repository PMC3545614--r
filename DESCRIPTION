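Package: palmgrade
Title: Color-Vision Ripeness Grading of Oil Palm Fresh Fruit Bunches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for automated ripeness grading of oil palm fresh
    fruit bunches (FFB) from color images. Fruit pixels are separated from
    spikes by K-means-derived color markers in the a*b* chromaticity plane,
    hue histograms of the fruit region form the feature vectors, principal
    component analysis optionally reduces them, and a multilayer perceptron
    with configurable transfer-function and output-coding combinations
    assigns one of four ripeness classes (unripe, underripe, ripe,
    overripe). Includes a seeded synthetic bunch-image generator with
    ground-truth masks and an experiment driver comparing full-feature
    and PCA-reduced classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    grDevices,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'palmgrade-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'colorspace.R'
    'io.R'
    'synthetic.R'
    'segmentation.R'
    'features.R'
    'pca.R'
    'mlp.R'
    'experiment.R'
    'show-methods.R'
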