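Package: dynphen
Title: Cross-Species Dynamical Phenotyping of Anaesthesia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterising how anaesthesia reshapes
    regional neural dynamics across species. Provides a curated catalogue of
    univariate time-series features, Hedge's g effect-size contrasts between
    wakefulness and anaesthesia, sign-consistency discovery against random-sign
    surrogate nulls, intrinsic-timescale estimation from the autocorrelation
    function, functional connectivity and dynamical-profile-similarity network
    measures, partial-least-squares correlation of dynamics-change maps with
    gene-expression maps under Moran spectral randomisation nulls, and a
    connectome-based dynamic mean-field model with feedback inhibition control,
    balloon-windkessel haemodynamics, and functional-connectivity-dynamics
    fitting of the global coupling. A synthetic-data module generates regional
    time series, spatially autocorrelated expression maps, and
    distance-dependent connectomes with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
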