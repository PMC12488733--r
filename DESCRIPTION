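Package: fruithsi
Title: Hyperspectral Imaging Pipeline for Non-Destructive Fruit Quality
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end Vis-NIR hyperspectral imaging workflow for predicting
    internal fruit quality traits (vitamin C, soluble solids content, soluble
    protein) from reflectance spectra. Covers ENVI cube input/output with
    white-reference correction, spectral-contrast region-of-interest
    segmentation with B-spline contour smoothing, Savitzky-Golay spectral
    smoothing, three-phase successive projections algorithm (SPA) wavelength
    selection with PRESS and F-test pruning, three small regression networks
    (CNN, CNN-BiGRU, CNN-BiGRU-Attention) trained with Adam, and an
    evaluation framework based on R-squared, RMSE and residual predictive
    deviation (RPD) with 7:3 internal splits and frozen-model external
    validation. A seeded synthetic-data generator emulates apple reflectance
    with analyte-linked absorption features so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    splines,
    signal,
    EBImage,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
biocViews: Regression, Preprocessing, FeatureExtraction, Spectrometry
Config/testthat/edition: 3
RoxygenNote: 7.3.3
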