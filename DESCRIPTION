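Package: dryscan
Title: Image-Based Monitoring of Fruit Slice Drying with a Moisture-Ratio Soft Sensor
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Batch processing of time-lapse tray photographs taken during
    fruit drying. Slices are segmented in HSV colour space, tracked across
    frames by centroid sorting on a fixed grid, and summarised by six
    appearance features (mean hue, saturation and value; normalised area and
    perimeter; compactness). The features drive a moisture-ratio soft sensor
    (NIPALS partial least squares and a 20-tree random forest, evaluated by
    5-fold cross-validation) and a PCA-based ranking of drying conditions by
    Euclidean distance of standardized relative appearance change from fresh
    fruit. A synthetic drying-scene generator with exact analytic ground
    truth makes every stage testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    randomForest,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Visualization, Regression, PrincipalComponent
RoxygenNote: 7.3.3
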