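Package: afmunfold
Title: Single-Molecule AFM Force Spectroscopy Analysis of Multi-State Protein Unfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for constant-velocity atomic force microscope
    (AFM) force spectroscopy of multi-domain protein constructs, built around
    the conformational unfolding of smooth-muscle myosin light chain kinase
    (smMLCK). Provides worm-like chain (WLC) elasticity and Bell-Evans rupture
    kinetics, inverse-WLC transformation of force-extension data into contour
    length space, total-variation denoising and rupture-event detection,
    Gaussian kernel density contour profiles with two-pass cross-correlation
    ensemble alignment, Gaussian peak fitting of contour-length increments,
    rupture-force statistics with Bell-Evans maximum likelihood fits and
    kernel-density modes, Fn3-anchored cross-dataset force normalization, and
    force-distance heatmaps. A seeded Monte-Carlo pulling simulator generates
    synthetic force-distance ensembles with the same multi-state structure
    (kinase states S0-S3, Fn3, Ig-like domains, tether detachment) for
    end-to-end validation of every analysis stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
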