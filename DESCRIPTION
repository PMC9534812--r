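Package: pentafluct
Title: Fluorescence Fluctuation and Single-Molecule Analysis of Membrane
    Receptor Pentamers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image correlation spectroscopy and single-molecule tools for
    quantifying the oligomeric state, mobility and co-diffusion of membrane
    receptor complexes such as pentameric glycine receptors. Implements
    masked raster image correlation spectroscopy (RICS/ARICS) with moving
    average detrending and molecular brightness estimation, temporal image
    (cross-)correlation spectroscopy (TICS/TICCS) for camera series,
    shift-resolved Pearson co-localization, stepwise photobleaching subunit
    counting with binomial mixture stoichiometry models, and window-based
    double-Gaussian single-channel current analysis. A seeded synthetic-data
    module simulates membrane diffusion imaged by a raster-scanned confocal
    beam or a TIRF camera, bleaching-step traces and two-level channel
    currents, so that every estimator is validated by closed-loop parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
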