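#' Define a cohort simulation scenario
#'
#' Collects every generative parameter of the family-cohort simulator: cohort
#' structure, allele-frequency model, assortative mating, polygenic score
#' (PGS) precision, and the phenotype model with direct, prenatal-parental,
#' postnatal-parental and sibling genetic effects per construct (Cog and
#' NonCog).
#'
#' Phenotypes of offspring are built as
#' \deqn{y = \sum_c [\beta_{direct,c} z_c + \beta_{prenatal,c}
#'   \bar{z}_c^{bio} + \beta_{postnatal,c} \bar{z}_c^{rear} +
#'   \beta_{sibling,c} \bar{z}_c^{cosib}] + shift \cdot (subpop - 1) +
#'   \varepsilon}
#' where \eqn{z_c} are true standardized scores, \eqn{\bar{z}^{bio}} /
#' \eqn{\bar{z}^{rear}} are biological / rearing mid-parent scores, and
#' \eqn{\bar{z}^{cosib}} is the mean score of rearing co-siblings.
#'
#' @param n_families number of families (couples) to simulate.
#' @param m_snps number of unlinked biallelic SNPs.
#' @param maf_low,maf_high ancestral minor-allele-frequency bounds in (0, 0.5].
#' @param n_subpops number of subpopulations.
#' @param fst Balding-Nichols divergence parameter (>= 0; 0 = no structure).
#' @param strat_env_shift additive phenotype shift per subpopulation index, in
#'   phenotype SD units.
#' @param am_rho target spousal correlation on the mating trait, in [0, 1).
#' @param mating_trait `"pgs"` (sum of true standardized scores) or
#'   `"phenotype"` (a parental phenotype built from the direct effects plus
#'   residual noise).
#' @param beta_direct_cog,beta_direct_noncog direct effect per SD of own true
#'   score.
#' @param beta_prenatal_cog,beta_prenatal_noncog effect per unit of
#'   *biological* mid-parent true score.
#' @param beta_postnatal_cog,beta_postnatal_noncog effect per unit of
#'   *rearing* mid-parent true score.
#' @param beta_sibling_cog,beta_sibling_noncog effect per unit of rearing
#'   co-sibling true score (summed over co-siblings by default, so the
#'   captured sibling effect accumulates with sibship size; see
#'   `sibling_aggregate`).
#' @param sibling_aggregate `"sum"` (default) or `"mean"`: whether each
#'   additional rearing co-sibling adds its own contribution or co-siblings
#'   contribute through their average score. Identical for two-offspring
#'   families.
#' @param pgs_precision squared correlation between measured and true score,
#'   in (0, 1]; 1 = the measured score is the true score.
#' @param offspring_per_family offspring per family: a single count in 1..3,
#'   or a vector of counts sampled uniformly per family (e.g. `1:3`).
#' @param dz_fraction,mz_fraction fraction of families whose first two
#'   offspring are DZ / MZ twins (requires >= 2 offspring).
#' @param adoption_fraction fraction of families contributing one adoptee,
#'   in [0, 0.5) per subpopulation (donor and rearing families are disjoint).
#' @param resid_sd residual phenotype SD.
#' @param age_range_offspring,age_range_parent uniform age ranges (years);
#'   pure covariates with no true effect.
#' @param seed master integer seed; all stages derive independent streams.
#'
#' @return An object of class `sim_scenario` (a validated list).
#' @seealso [simulate_cohort()], [bias_scenarios()]
#' @examples
#' sc <- sim_scenario(n_families = 200, m_snps = 50, seed = 1)
#' sc
#' @export
sim_scenario <- function(n_families = 20000,
                         m_snps = 1000,
                         maf_low = 0.05,
                         maf_high = 0.5,
                         n_subpops = 1,
                         fst = 0,
                         strat_env_shift = 0,
                         am_rho = 0,
                         mating_trait = c("pgs", "phenotype"),
                         beta_direct_cog = 0.15,
                         beta_direct_noncog = 0.15,
                         beta_prenatal_cog = 0,
                         beta_prenatal_noncog = 0,
                         beta_postnatal_cog = 0,
                         beta_postnatal_noncog = 0,
                         beta_sibling_cog = 0,
                         beta_sibling_noncog = 0,
                         sibling_aggregate = c("sum", "mean"),
                         pgs_precision = 1,
                         offspring_per_family = 2,
                         dz_fraction = 0,
                         mz_fraction = 0,
                         adoption_fraction = 0,
                         resid_sd = 1,
                         age_range_offspring = c(10, 18),
                         age_range_parent = c(35, 55),
                         seed = 1) {
  mating_trait <- match.arg(mating_trait)
  sibling_aggregate <- match.arg(sibling_aggregate)
  n_families <- check_count(n_families, "n_families", min = 2L)
  m_snps <- check_count(m_snps, "m_snps", min = 1L)
  n_subpops <- check_count(n_subpops, "n_subpops", min = 1L)
  check_prob(maf_low, "maf_low", lo = 0, hi = 0.5, lo_open = TRUE)
  check_prob(maf_high, "maf_high", lo = 0, hi = 0.5, lo_open = TRUE)
  if (maf_low > maf_high) stop_param("`maf_low` must be <= `maf_high`")
  if (!is.numeric(fst) || length(fst) != 1L || fst < 0) {
    stop_param("`fst` must be a single number >= 0")
  }
  check_prob(am_rho, "am_rho", lo = 0, hi = 1, hi_open = TRUE)
  check_prob(pgs_precision, "pgs_precision", lo = 0, hi = 1, lo_open = TRUE)
  check_prob(dz_fraction, "dz_fraction")
  check_prob(mz_fraction, "mz_fraction")
  if (mz_fraction + dz_fraction > 1) {
    stop_param("`mz_fraction` + `dz_fraction` must be <= 1")
  }
  check_prob(adoption_fraction, "adoption_fraction", hi = 1, hi_open = TRUE)
  if (!is.numeric(offspring_per_family) ||
      any(offspring_per_family != round(offspring_per_family)) ||
      any(offspring_per_family < 1) || any(offspring_per_family > 3)) {
    stop_param("`offspring_per_family` must be count(s) in 1..3")
  }
  if (!is.numeric(resid_sd) || length(resid_sd) != 1L || resid_sd < 0) {
    stop_param("`resid_sd` must be a single number >= 0")
  }
  seed <- check_count(seed, "seed", min = 0L)

  sc <- list(
    n_families = n_families, m_snps = m_snps,
    maf_low = maf_low, maf_high = maf_high,
    n_subpops = n_subpops, fst = fst, strat_env_shift = strat_env_shift,
    am_rho = am_rho, mating_trait = mating_trait,
    beta_direct_cog = beta_direct_cog,
    beta_direct_noncog = beta_direct_noncog,
    beta_prenatal_cog = beta_prenatal_cog,
    beta_prenatal_noncog = beta_prenatal_noncog,
    beta_postnatal_cog = beta_postnatal_cog,
    beta_postnatal_noncog = beta_postnatal_noncog,
    beta_sibling_cog = beta_sibling_cog,
    beta_sibling_noncog = beta_sibling_noncog,
    sibling_aggregate = sibling_aggregate,
    pgs_precision = pgs_precision,
    offspring_per_family = as.integer(offspring_per_family),
    dz_fraction = dz_fraction, mz_fraction = mz_fraction,
    adoption_fraction = adoption_fraction,
    resid_sd = resid_sd,
    age_range_offspring = age_range_offspring,
    age_range_parent = age_range_parent,
    seed = seed
  )
  class(sc) <- "sim_scenario"
  sc
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario>\n")
  cat(sprintf("  families: %d  SNPs: %d  offspring/family: %s\n",
              x$n_families, x$m_snps,
              paste(x$offspring_per_family, collapse = "/")))
  cat(sprintf("  subpops: %d (fst=%g, env shift=%g)  am_rho=%g on %s\n",
              x$n_subpops, x$fst, x$strat_env_shift, x$am_rho,
              x$mating_trait))
  cat(sprintf("  beta direct (%g, %g)  prenatal (%g, %g)  postnatal (%g, %g)  sibling (%g, %g)\n",
              x$beta_direct_cog, x$beta_direct_noncog,
              x$beta_prenatal_cog, x$beta_prenatal_noncog,
              x$beta_postnatal_cog, x$beta_postnatal_noncog,
              x$beta_sibling_cog, x$beta_sibling_noncog))
  cat(sprintf("  pgs precision: %g  MZ/DZ/adopted fractions: %g/%g/%g  seed: %d\n",
              x$pgs_precision, x$mz_fraction, x$dz_fraction,
              x$adoption_fraction, x$seed))
  invisible(x)
}

#' Read / write a scenario as YAML
#'
#' @param scenario a [sim_scenario()] object.
#' @param path file path.
#' @return `read_scenario()` returns a `sim_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_scenario, vals)
}
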