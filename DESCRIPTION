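Package: twaskit
Title: Transcriptome-Wide Association Testing from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for transcriptome-wide association studies (TWAS) driven
    entirely by GWAS summary statistics and a genotyped expression reference
    panel: REML estimation of cis SNP-heritability of expression with a
    likelihood-ratio screen, training of SNP-to-expression predictors by five
    methods (BLUP, lasso, elastic net, single best eQTL, spike-and-slab
    sparse Bayes) with fivefold cross-validated model selection, the
    summary-statistics TWAS z-statistic with ridge-regularized reference LD,
    a case-only test for disease-subtype heterogeneity of expression effects,
    and conditional-and-joint analyses of multi-gene regions at the z-score
    level. A synthetic-data module generates LD-structured genotype panels,
    cis-heritable expression and subtype-stratified GWAS z-scores with known
    truth so the whole pipeline can be exercised and calibrated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
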