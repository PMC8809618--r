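Package: wormMotility
Title: Longitudinal Motility Quantification and Acquisition-Protocol
    Simulation for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying early-adult movement decline of
    Caenorhabditis elegans individuals confined to small circular arenas.
    Provides a calibrated stochastic generator of per-second centroid
    trajectories with age-declining, individually variable activity;
    conversion of trajectories to displacement series and 3-hour block or
    daily movement totals with stimulus-exclusion bookkeeping; simulation
    of image-acquisition protocols (single snapshot, daily video, hybrid
    multipass) by temporal subsampling; decline statistics (ordinary
    least-squares fits with Wald tests, within-block bootstrap confidence
    intervals, coefficients of variation, pairwise day correlations); and
    bacterial-lawn segmentation of arena images by two-component
    Gaussian-mixture fitting of the intensity histogram.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'arena-images.R'
    'decline-stats.R'
    'simulate.R'
    'io.R'
    'lawnseg.R'
    'motility.R'
    'protocols.R'
    'pipeline.R'
    'wormMotility-package.R'
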