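Package: plnnfc
Title: Interpretable Piecewise-Linear Neural Networks for Functional
    Connectivity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-group classification of resting-state functional
    connectivity profiles with a small fully connected neural network
    built from fc-BatchNorm-LeakyReLU blocks, together with its exact
    per-instance interpretation: because every activation is piecewise
    linear and batch normalization is an affine map at test time, the
    fitted network restricted to one activation region is a plain linear
    classifier whose weights and intercept are recovered in closed form.
    Includes Pearson/Fisher-z edge feature extraction from ROI time
    series, stratified cross-validation with the usual confusion-matrix
    metrics, group-level decision-feature mining by top-K occurrence
    thresholding, perturbation ("hacking") evaluation of attributed
    features against a linear-SVM baseline, per-edge group statistics,
    and a synthetic two-group cohort generator with planted connectivity
    differences for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
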