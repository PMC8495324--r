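Package: peaMixSel
Title: Phenotypic and Genomic Selection Strategies for Pea-Cereal Intercropping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic toolkit for comparing selection strategies that
    target pea grain yield in mixed stands (intercrops) with small-grain cereals.
    Implements a seeded simulator of recombinant inbred line (RIL) populations and
    split-plot variety trials in pure stand (PS) and mixed stand (MS); balanced
    ANOVA and variance-component estimation with broad-sense line-mean
    heritability; Robertson cross-condition and Itoh-Yamada cross-year genetic
    correlations; stepwise construction of an indirect selection index; predicted
    and realized relative-efficiency estimators for indirect, index-based and
    genomic selection; 012 genotype-matrix filtering, k-nearest-neighbour
    imputation and Astle-Balding kinship; ridge-regression BLUP and GBLUP genomic
    prediction with stratified inter-environment cross-validation; and a
    single-marker GWAS with population covariates, genomic control and Bonferroni
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
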