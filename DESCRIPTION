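Package: chpvalid
Title: Candidate SNP Validation and Pathway Analysis for Cold-Heat Pattern Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation pipeline for GWAS-reported candidate SNPs against
    cold-heat pattern (C-HP) questionnaire scores in small cohorts:
    catalog filtering, covariate-adjusted linear regression with
    Freedman-Lane residual-permutation significance, linkage-disequilibrium
    pruning and clumping, genotype principal component analysis on a
    variance-standardized relationship matrix, gene-set over-representation
    with Monte-Carlo combined scores, Jaccard pathway-similarity networks,
    and control-trait specificity comparison. Includes synthetic-data
    generators (LD-block genotypes, Balding-Nichols structured panels,
    planted phenotype effects) so the full pipeline is testable without
    cohort data, plus the published heat- and cold-pattern candidate SNP
    tables as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
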