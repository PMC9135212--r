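Package: pestsurv
Title: Spatiotemporal Surveillance Analysis of Urban Pest Complaint Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of municipal pest-complaint surveillance data at the
    neighbourhood level: harmonic seasonal regression with linearly varying
    amplitude for monthly complaint series, indirect standardization to
    standardized incidence ratios (SIR), and Bayesian hierarchical
    spatiotemporal Poisson models with BYM spatial convolution, second-order
    random-walk temporal effects and Knorr-Held style space-time interactions
    (types I-III), fitted by Metropolis-within-Gibbs MCMC and compared by the
    deviance information criterion. Includes a synthetic-data generator for
    areal lattices and complaint panels, readers for 311-style administrative
    CSV exports and GeoJSON neighbourhood polygons, and a seeded end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
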