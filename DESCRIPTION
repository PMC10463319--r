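Package: splitmr
Title: Split-Sample Mendelian Randomization Pipelines for Multimorbidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating causal effects of education, body mass
    index, lifetime smoking and alcohol consumption on multimorbidity using
    split-sample Mendelian randomization. Provides a synthetic biobank
    generator with known structural parameters (LD-blocked genotypes,
    questionnaire-like phenotypes, liability-threshold condition flags),
    phenotype derivation (years of education, lifetime smoking index,
    weekly alcohol units, multimorbidity counts and the Cambridge
    multimorbidity score), split-sample GWAS with LD clumping and
    standardized polygenic risk scores, robust multivariable regression and
    two-stage least squares (including multivariable MR), summary-statistic
    sensitivity estimators (IVW, MR-Egger, unweighted median, simple mode),
    fixed-effects meta-analysis with I-squared, mediation analysis with
    bootstrap proportion-mediated intervals and a parametric g-formula
    sensitivity, and additive-interaction MR with product-score instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lmtest,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
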