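Package: rhapscan
Title: Rare-Haplotype Sliding-Window Association Scans with a Logistic
    Bayesian LASSO
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-wide case-control haplotype association analysis over
    sliding windows of SNPs. Reconstructs haplotype frequencies from
    unphased genotypes by an EM algorithm, fits a retrospective-likelihood
    logistic Bayesian LASSO with double-exponential shrinkage priors and
    Bayes-factor tests for individual (including rare) haplotypes, and
    provides frequentist comparators (haplotype score test, EM-GLM Wald
    tests with pooling, single-SNP logistic scan). Includes
    permutation-based false-positive assessment and a synthetic
    case-control cohort generator with rare-haplotype-rich pools for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
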