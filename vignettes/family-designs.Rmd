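---
title: "Estimating direct and parental indirect genetic effects with family-based polygenic score designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating direct and parental indirect genetic effects with family-based polygenic score designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsfam)
```

## The problem

A polygenic score (PGS) association with an outcome measured in unrelated
individuals -- the *population effect* -- conflates two very different causal
routes. The *direct genetic effect* runs from a person's own genotype to their
own outcome. The *parental indirect genetic effect* ("genetic nurture") runs
from the parents' genotypes, through the environment the parents provide, to
the child's outcome: parental alleles the child never inherited can still
shape the rearing environment. On top of these, assortative mating and
population stratification inflate population associations without any causal
pathway through the index person at all.

`pgsfam` implements the three family-based designs that separate these
components for two polygenic scores analysed jointly (labelled `cog` and
`noncog`, for a cognitive-skills score and the residual non-cognitive score
obtained by GWAS-by-subtraction), together with a cohort simulator that
generates data in which the true components and biases are known.

## The three designs

All models are ordinary linear regressions (`lm()`), with covariates sex,
age, sex x age and optionally ancestry principal components; outcomes and
scores are standardized per analysis sample.

**Sibling design.** Two regressions on the same genotyped-sibling rows:

* within/between: `y ~ (PGS - family mean) + family mean` for both
  constructs jointly;
* population: `y ~ PGS` for both constructs.

The within-family coefficient is the direct effect (Mendelian segregation
randomizes genotypes within a sibship); the indirect effect is
`population - within`.

**Adoption design.** The population regression fitted separately in adoptees
and in individuals reared by their biological parents, with scores scaled
within each group. Adoptees share no alleles by descent with their rearing
parents, so their coefficient is a direct effect; the indirect effect is the
non-adopted (population) coefficient minus the adoptee coefficient.

**Trio (non-transmitted alleles) design.** With both parents genotyped and
transmission phased, each parent's score splits into a transmitted and a
non-transmitted part. The design regresses the outcome on the transmitted
composite (paternal + maternal transmitted scores) and the non-transmitted
composite (by default the *average* of the two parental non-transmitted
scores; a `sum` convention is available and differs only by a factor that
the standardization absorbs). The non-transmitted coefficient is the
indirect effect -- non-transmitted alleles can only act through the
environment -- and the direct effect is `beta_T - beta_NT`.

Derived ratios (`indirect/population`, `indirect/direct`), Z-tests for
contrasts, family-resampled nonparametric bootstrap intervals and
random-effects meta-analysis across designs (`metafor`, with design as a
random intercept) complete the inferential surface.

## The cohort simulator

`sim_scenario()` + `simulate_cohort()` generate two-generation cohorts:

* **Loci.** `m_snps` unlinked biallelic SNPs; ancestral frequencies uniform
  on `[maf_low, maf_high]`; subpopulation frequencies from the
  Balding-Nichols distribution with divergence `fst`. The designs depend
  only on transmission, so linkage and recombination maps are deliberately
  out of scope.
* **Founders.** `2 * n_families` founders with Bernoulli haplotypes at
  their subpopulation frequencies. Subpopulations are assigned in balanced
  blocks within each sex so that within-subpopulation spousal matching
  always has equal numbers of prospective fathers and mothers.
* **True scores and weights.** Gaussian per-SNP weights (SD `1/sqrt(m)`)
  define true scores, standardized within the founder pool. Measured-score
  imprecision is modelled at the weight level: `make_noisy_weights()` mixes
  the true weights with independent Gaussian noise calibrated so the
  squared correlation between measured and true scores equals
  `pgs_precision`. This represents a finite-GWAS score without simulating
  the GWAS itself. The noise weights form a heritable score of their own,
  so attenuation is identical within and between families -- which is what
  makes the designs consistent under imprecision.
* **Assortative mating.** One round of within-subpopulation Gaussian
  coupling: males' mating-trait normal ranks are blurred with noise
  (`w = rho * x + sqrt(1 - rho^2) * e`) and females are matched by rank on
  `w`, which realizes a spousal correlation of about `am_rho` on the mating
  trait (the standardized sum of the two construct scores, or a
  direct-effect phenotype). This is the disequilibrium regime; no
  multi-generation equilibrium is simulated.
* **Meiosis.** Independent fair choice of one parental allele per locus,
  with the transmitted-haplotype index recorded per offspring, parent and
  locus. MZ co-twins duplicate one meiosis; DZ co-twins are independent
  meioses sharing an age.
* **Adoption.** A fraction of families donate their first offspring to a
  rearing family drawn from a *disjoint* set of families (one adoptee per
  rearing family, own offspring retained; the disjointness caps the
  fraction at 0.5). Placement is random *within subpopulation*: adoptees
  are genetically unrelated to their adoptive parents, but they experience
  the same subpopulation-level rearing environment as everyone else. This
  choice is what gives the adoption design its robustness to
  stratification -- the environmental confound hits adoptees and
  non-adoptees alike and cancels in the population-minus-direct
  subtraction. Cross-subpopulation placement would instead leave the
  adoption design fully confounded.
* **Phenotype.** For each offspring and construct:
  direct (`beta_direct * z_child`), prenatal (`beta_prenatal *`
  *biological* mid-parent score), postnatal (`beta_postnatal *` *rearing*
  mid-parent score), sibling (`beta_sibling *` rearing co-sibling scores),
  a `strat_env_shift * (subpop - 1)` environmental shift tied to the
  rearing family's subpopulation, and Gaussian noise (`resid_sd`).
  Adoptees therefore keep prenatal effects from their biological parents
  and receive postnatal effects from their adoptive parents; effects in
  the window between birth and adoption are merged into the prenatal
  component.
* **Sibling aggregation.** The sibling term defaults to the *sum* of
  co-sibling scores (`sibling_aggregate = "sum"`), so the captured sibling
  effect accumulates with sibship size; a `"mean"` variant is available.
  The sum is what the number-of-siblings moderation analysis presumes --
  under the mean formulation that analysis is powerless by construction
  (the PGS captures the same amount of sibling effect at any sibship size
  above one). The two are identical for two-offspring families, which is
  all the other analyses use.
* **Covariates.** Sex alternates within a family (offset by family parity
  so first-borns, the adoptee pool, are an even mix); ages are uniform
  within configurable ranges. Both are pure covariates with zero true
  effect.

Every stage draws from an independent stream derived from the scenario
seed, so cohorts are bit-reproducible and replicates are independent under
a counter scheme regardless of execution order.

### What the simulator does *not* emulate

Linkage disequilibrium and LD-aware weights, genotyping error and
imputation, multi-generation assortment or dynastic effects beyond the
parents, selective adoptive placement, and participation bias. Passing the
test suite therefore shows that the estimators do what they claim under
the stated generative model -- not that real-cohort estimates are free of
the corresponding real-world complications.

## The design-comparison experiment

`bias_scenarios()` defines six named scenarios -- `no_bias` (postnatal
indirect effect only), `prenatal`, `sibling_effect`, `assortment`,
`stratification`, `combined` -- and `run_grid()` fits all three designs to
replicate cohorts of each. The reference scale is 20,000 families by 100
replicates; a `desk` preset (2,000 families by 20 replicates) covers
interactive use and the test suite, at the cost of Monte-Carlo error only.

The scenario parameters are *demonstration* settings chosen once so each
mechanism is visible at the desk scale:

* true-score direct effect 0.3 with `pgs_precision = 0.25`, so the
  measured-score direct effect is about `0.3 * sqrt(0.25) = 0.15`, the
  scale reported for educational outcomes in family cohorts. The imprecise
  score is not cosmetic: the assortative-mating bias channel that
  *differentiates* the sibling design is proportional to
  `beta_direct * (1 - precision) * spousal r` and vanishes for a perfect
  score;
* indirect components 0.2 (about 0.05 on the measured scale);
* `am_rho = 0.5`, the strength of educational phenotypic assortment;
* two subpopulations with `fst = 0.1` and a 1 SD environment shift.

Expected patterns, all checked by the test suite:

1. **no bias**: the three designs agree on the indirect effect;
2. **prenatal-only**: sibling and trio estimate the prenatal component,
   adoption is blind to it (adoptees' postnatal environment comes from
   genetically unrelated parents);
3. **sibling effects** mainly inflate the sibling design -- the co-sibling
   contribution enters its population term *and* depresses its
   within-family term -- while adoption and trio are inflated mildly and
   *equally* (through their population/non-transmitted terms), so their
   contrast is unaffected;
4. **assortative mating** biases the adoption design least; the per-cohort
   truth cancels in the paired sibling-minus-adoption difference, which is
   the statistic tested;
5. **stratification** (PCs withheld) biases the adoption design least; the
   *sign* of the bias depends on the weight draw (random weights may
   correlate either way with the frequency divergence), so magnitudes are
   compared per replicate; including 10 ancestry PCs shrinks the sibling
   and trio biases.

```{r, eval = FALSE}
grid <- bias_scenarios(preset = "desk")
res <- run_grid(grid, seed = 1)
summarize_grid(res)        # boxplot statistics per scenario x design
report_grid(res, "out/")   # markdown + TSV report
```

## Numerical and statistical choices

* **Standardization.** Outcomes are standardized once per design subset
  (not per group): for the adoption design this keeps the two groups'
  coefficients on one scale so their difference is meaningful. Scores are
  scaled per the design rule (sibling sample; adoptee/non-adopted groups
  separately; trio composites separately). Standardizing a zero-variance
  quantity is always an explicit error flagged as degenerate.
* **Bootstrap.** Ordinary nonparametric, default `B = 10000`, resampling
  whole families for the sibling/trio/quad designs (both sibling-design
  regressions are refit on the same bootstrap sample) and persons within
  the adoptee/non-adopted strata for the adoption design; row-level
  resampling is available as a flag. "Bias-corrected normal" intervals are
  `2 * estimate - mean(draws) +/- z * SE(draws)`; percentile intervals are
  an option. Replicates that fail to fit are dropped and counted; more
  than 1% failures is an error.
* **Ratios.** `indirect/population` and `indirect/direct` are propagated
  through the paired bootstrap draws; a denominator below tolerance flags
  the ratio unstable and suppresses its CI rather than reporting a wild
  interval.
* **Meta-analysis.** Two-level REML via `metafor::rma.mv` with a design
  random intercept when more than one design contributes, collapsing to
  standard random-effects otherwise; a fixed-effect pool is available.
  Exact numerical equivalence with a fully multivariate mixed
  meta-analysis is not claimed.
* **PCs.** Fitted on one founder per family (a maximal unrelated set) and
  projected onto everyone, via an exact Gram-matrix/thin-SVD route;
  zero-variance SNPs are dropped with a message, and asking for more
  components than the rank supports is an error.
* **Naive SEs.** The analytic SEs attached to subtraction-based quantities
  (sibling and adoption indirect effects) combine the two regressions' SEs
  in quadrature and ignore their covariance; they are reported for
  orientation only, and the bootstrap is the authoritative uncertainty.
* **Sibling-design rows.** Families contribute *all* genotyped siblings
  (not a sampled pair), and the family mean is taken over the included
  siblings; the two sibling-design regressions always use identical rows
  and covariates so the subtraction is internally consistent.
* **Degenerate covariates** (e.g. a constant platform column in simulated
  data) are dropped with a message rather than an error; collinear *focal*
  predictors raise an error naming the offending columns.

## Problem sizes used by the checks

The packaged checks run the desk-scale grid (2,000 families x 20
replicates, six scenarios), single 20,000-family cohorts for parameter
recovery, a genotype-free multivariate-normal oracle of one million
offspring for the indirect-effect plim, 2,000-replicate bootstraps for the
SE cross-check, and 5,000-family cohorts for the random-mating nulls
(sibling ICC 0.5, spousal correlation 0). These sizes are the package's
own choices balancing Monte-Carlo error against runtime; the reference
experiment scale remains available through `bias_scenarios(preset = "reference")`.

## Known limitations

* The adoption design's robustness claims are conditional on random
  placement within subpopulation; selective placement correlated with the
  biological family's scores would bias it downward, and is not modelled.
* One round of assortment understates equilibrium assortative-mating
  biases; multi-generation equilibrium is out of scope.
* The GWAS-by-subtraction module implements only the deterministic
  two-latent-factor path algebra (solving per-SNP `Cog`/`NonCog` effects
  from EA/CP effects and regenerating consistent summary statistics); LDSC
  sampling covariance, effective-N computation and genomic-control
  corrections are out of scope, and its default loadings are package
  choices, not estimates.
* Analytic SEs for subtracted quantities ignore cross-regression
  covariance (see above); use the bootstrap.
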