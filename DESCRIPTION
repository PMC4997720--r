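Package: stratcomp
Title: A Priori Comparison of Regression Modelling Strategies for Clinical Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing regression model-building strategies before a
    final prediction model is chosen. A wrapper approach repeatedly bootstraps a
    development data set, fits two candidate strategies to each resample, and
    evaluates both fitted models in the original data (sum of squared errors for
    linear models, -2 log-likelihood for logistic models); the resulting
    comparison distribution is summarized by its victory rate, median and
    interquartile range. Includes implementations of six model-building
    strategies (unshrunken least-squares/maximum-likelihood fits, heuristic
    shrinkage, split-sample shrinkage, k-fold cross-validation shrinkage,
    bootstrap shrinkage and Firth-penalized logistic regression),
    synthetic-data generators emulating deep-vein-thrombosis diagnostic data,
    and simulation sweeps over events-per-variable, observations-per-variable
    and explained-variance grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
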