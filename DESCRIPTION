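Package: cytoploidy
Title: DNA Ploidy Analysis by Image Cytometry with Flow-Cytometry Calibration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Per-nucleus DNA-content measurement from fluorescence images of
    propidium-iodide stained nuclei (integrated optical density with local
    annulus background correction, pixel-count area, gradient-based
    granularity), identification of debris/2N/4N populations by fuzzy c-means
    clustering with classification-uncertainty filtering, DNA-histogram peak
    estimation by modal bin and Gaussian fitting, and cohort-level calibration
    of the image-cytometry intensity scale against flow-cytometry reference
    peaks (naive mean scale and linear regression with residual diagnostics
    and intensity-outlier exclusion). Includes a synthetic paired FCM/ICM
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    cluster,
    e1071,
    knitr
biocViews: CellBiology, FlowCytometry, Clustering, Regression, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
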