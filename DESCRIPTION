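Package: gpwheat
Title: Multi-Trait Multi-Environment Genomic Prediction for Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic selection toolkit for replicated multi-environment
    breeding trials: marker quality control and mean imputation, VanRaden and
    centered-IBS genomic relationship matrices, per-environment and
    across-environment adjusted means (BLUEs/BLUPs) with REML variance
    components and broad-sense heritability, spectral-REML GBLUP (ridge
    regression on markers), Bayesian multi-trait and multi-trait
    multi-environment Gibbs samplers with missing-phenotype augmentation,
    CV1/CV2/MTME cross-validation schemes, sparse-testing allocation designs,
    and a synthetic breeding-trial generator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    vcfR,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
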