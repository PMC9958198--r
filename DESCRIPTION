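Package: pollenfuse
Title: Explainable Multi-Modal Deep Learning for Single-Particle Pollen
    Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@pollenfuse.org",
    role = c("aut", "cre"))
Description: Tools for classifying airborne pollen from single-particle
    optical fingerprints (elastic light scattering images, laser-induced
    fluorescence spectra and fluorescence lifetime traces) and for explaining
    the classifier's decisions.  Implements the signal filtering and
    alignment pipeline for Rapid-E style particle records, a three-branch
    fusion convolutional network trained with balanced stochastic gradient
    descent, Integrated Gradients attribution with a zero baseline, per-class
    aggregation of attributions into ranked feature summaries and symbolic
    heatmaps, and cross-examination of spectral attributions against
    laboratory reference fluorescence spectra via rectangular-kernel
    resampling and principal component analysis.  A synthetic particle
    generator with planted class-discriminative structure supports fully
    reproducible end-to-end analyses without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), methods
Imports:
    stats,
    utils,
    Rcpp,
    yaml,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Software, Spectroscopy, SingleCell
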