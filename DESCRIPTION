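Package: ewlmm
Title: Bayesian Phylogenetic Longitudinal Models of Evaporative Water Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and Bayesian inference for longitudinal
    body-mass experiments on amphibian evaporative water loss. Generates
    synthetic mass trajectories under a 2x2 water-availability by temperature
    design with nested random effects and Gaussian-kernel temporal
    autocorrelation; applies excretion correction, exclusion and imputation
    rules; builds a composite phylogenetic plus temporal residual covariance
    from Newick tree samples; fits a hierarchical Gaussian model by
    Hamiltonian Monte Carlo with random effects marginalised into the
    covariance; and reports posterior marginal effects, direction
    probabilities, rate conversions and variance ratios. Includes a
    generalised least squares oracle and a parameter-recovery experiment for
    validating the sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    phytools
Config/testthat/edition: 3
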