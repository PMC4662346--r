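Package: provgall
Title: Provenance Effects on Oak Gall Abundance with Control for Population Nonindependence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing herbivore (cynipid gallwasp) abundance across
    tree provenances grown in a common-garden trial. Estimates pairwise
    Weir-Cockerham F_ST from microsatellite genotypes, tests isolation by
    distance with a Mantel permutation test, predicts a distance-based
    pseudo-F_ST (GeoF_ST) for provenances lacking genotypes, and builds
    provenance variance-covariance matrices (identity, 1-F_ST, 1-GeoF_ST).
    Fits Bayesian Poisson and Gaussian mixed models by MCMC with
    covariance-structured random effects, a nugget term and an
    observation-level overdispersion (UNIT) term, and turns the posteriors
    into variance components, marginal R-squared, pMCMC, VIF and
    FDR-adjusted significance reports. Includes a synthetic provenance-trial
    generator with known ground truth so the full pipeline can be exercised
    and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    geosphere,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    car,
    jsonlite
Config/testthat/edition: 3
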