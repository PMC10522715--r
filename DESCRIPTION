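Package: mapdyn
Title: Mapping Neurophysiological Dynamics to Cortical Micro-Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating regional neurophysiological time-series
    phenotypes to cortical micro-architectural maps. Provides a curated
    time-series feature catalogue (distributional, autocorrelation,
    fluctuation, spectral, model-fit, multiscale and entropy families),
    Welch spectral estimation with knee-mode aperiodic parameterization
    and intrinsic timescales, principal-component gradients, partial
    least squares latent-variable mapping with spatial-autocorrelation
    preserving spin permutation inference, bootstrap loading reliability,
    distance-dependent cross-validation, and a toy multi-donor microarray
    expression-map pipeline. Includes synthetic-data generators with a
    planted dynamics/micro-architecture latent axis for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
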