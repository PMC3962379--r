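Package: spatialews
Title: Spatial Early-Warning Signals of Ecological Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes spatial early-warning indicators of approaching
    ecological tipping points from 2D raster snapshots: spatial variance and
    skewness, Moran's I spatial correlation, 2D periodogram with radial and
    angular spectra and spectral reddening, patch-size distributions with
    maximum-likelihood fits of heavy-tailed families, and periodic-pattern
    morphology classification. Provides surrogate null models (reshuffling,
    matched-moment Gaussian fields, coarse-graining) and analytic chi-squared
    spectral bands that give the indicators statistical meaning, Kendall and
    Pearson trend statistics along degradation gradients, a decision workflow
    that routes a data set to the appropriate indicator battery, and three
    stochastic spatial simulators of vegetation dynamics (local positive
    feedback lattice, facilitation cellular automaton, scale-dependent
    feedback Turing model) used to generate test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    igraph,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
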