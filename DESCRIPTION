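Package: pgsfam
Title: Family-Based Polygenic Score Designs for Direct and Indirect
    Genetic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation toolkit for family-based polygenic
    score (PGS) analyses of direct and parental indirect genetic effects
    ("genetic nurture"). Simulates two-generation family cohorts with
    phased transmission, monozygotic and dizygotic twins, adoption,
    assortative mating and Balding-Nichols population stratification;
    computes own, transmitted, non-transmitted, mid-parent and
    within-family polygenic scores with design-specific standardization;
    fits the sibling (within/between), adoption-contrast and trio
    non-transmitted-allele designs plus sibling-effect sensitivity models;
    provides family-resampled nonparametric bootstrap intervals, ratio and
    Z-test statistics, random-effects meta-analysis across designs, a
    simplified per-SNP GWAS-by-subtraction solver, and a scenario-grid
    runner comparing how the three designs recover indirect genetic
    effects under prenatal effects, sibling effects, assortative mating
    and population stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    metafor,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
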