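Package: kcrit
Title: Sustainable Rates of Phenotypic Adaptation Under a Moving Optimum
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-based, multi-locus quantitative-genetic Monte Carlo
    simulation of diploid populations tracking a directionally moving
    environmental optimum. Starting conditions are drawn from empirically
    calibrated probability densities (phenotypic variance, heritability,
    mutational heritability, strength of stabilising selection, rate of
    environmental change). Provides per-population statistics (trait-scaled
    rates of change, lag behind the optimum, extinction and 50%-mortality
    times, the critical rate of environmental change k_c), ensemble
    orchestration with mutation-adjusted weighted medians, and a phenology
    comparison stage with a synthetic longitudinal-series generator.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
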