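Package: cyclofi
Title: Cyclicity Analysis and Resting-State Functional Interactivity Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Compares four pairwise resting-state functional interactivity
    measures for multivariate (ROI x time) BOLD-like series: cyclicity
    analysis via skew-symmetric signed-area lead matrices and their spectral
    temporal ordering, zero-lag Pearson correlation, lagged cross-correlation
    (extremal correlation and time-delay matrices), and dynamic time warping
    distance. Includes the associated preprocessing variants (detrending,
    end-matching, quadratic-variation/norm/std scaling, zero-phase Bessel
    band-pass filtering, global signal regression), cross-visit individual
    fingerprinting with Gorodkin's multi-class Matthews correlation, group
    classification (discriminant analysis, kernel and sparse L1 support
    vector machines, a small convolutional network with variational
    autoencoder augmentation), two-dimensional embedding diagnostics (t-SNE,
    Isomap), and a synthetic generator for cyclic time-series panels with
    known temporal ordering, subject signatures and injectable group effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
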