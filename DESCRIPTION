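Package: gsimix
Title: Bayesian Genetic Stock Identification with Assignment Calibration
    and Body-Condition Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-stock analysis of SNP genotypes by Gibbs sampling over
    latent individual origins, stock proportions, and allele frequencies
    (the Pella-Masuda model family), with multi-chain execution and
    Gelman-Rubin convergence checks. Includes threshold-based individual
    assignment to stock groups, a known-mixture holdout procedure for
    calibrating assignment error rates, AICc-based comparison of grouped
    length-mass body-condition regressions, and a synthetic-data generator
    (Balding-Nichols population structure) so the whole pipeline is
    testable without external genotype data.
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
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
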