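Package: bayesw
Title: Bayesian Spike-and-Slab Weibull Regression for Censored Age-at-Onset
    Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Whole-genome Bayesian analysis of censored, optionally
    left-truncated time-to-event phenotypes under a Weibull accelerated
    failure time model. Marker effects carry a grouped Dirac spike-and-slab
    mixture prior; the Gibbs sampler combines derivative-free adaptive
    rejection sampling for the non-conjugate conditionals with adaptive
    Gauss-Hermite quadrature for the mixture-membership marginal
    likelihoods, and exploits the three-valued genotype coding for sparse
    updates. Includes a bulk-synchronous-parallel sampler variant, a
    synthetic genotype/phenotype generator (generalised-gamma errors with
    controlled censoring), PLINK 1 binary input, and post-processing:
    log-scale SNP heritability, posterior probability of window variance
    (PPWV) with LD clumping, genomic prediction with posterior predictive
    intervals, precision-recall, and Harrell's C.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    pracma,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
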