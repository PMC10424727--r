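Package: ecgtracks
Title: Three-Track ECG Classification with Efficiency Profiling and
    Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classification of cardiovascular disease from ECG recordings
    along three tracks: deep image classifiers (ResNet50, DenseNet121) over
    rasterized Poincare diagrams of NN intervals, one-dimensional
    convolutional networks (a 12-block CNN and a 1D ResNet) over raw
    signals, and gradient-boosted trees over an efficient time-series
    feature set. Includes WFDB-dialect record I/O, a Hamilton R-peak
    detector, reproducible dataset splits, macro-averaged evaluation
    metrics with cross-validation, an inference efficiency harness
    (energy, CO2-equivalent, latency), GradCAM saliency for 1D and 2D
    models, and a controllable synthetic annotated ECG generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    signal,
    xgboost,
    lhs,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'accessors.R'
    'nn-engine.R'
    'io.R'
    'synth.R'
    'preprocess.R'
    'poincare.R'
    'nets.R'
    'tsboost.R'
    'evalkit.R'
    'interpret.R'
    'pipeline.R'
    'ecgtracks-package.R'
    'RcppExports.R'
RoxygenNote: 7.3.3
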