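# Shared fixtures: small scenarios built in code, with a per-session cache so
# expensive cohorts are simulated once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# all generative effects off: phenotype is pure noise
null_scenario <- function(n_families = 2000, m_snps = 200, seed = 101, ...) {
  args <- list(n_families = n_families, m_snps = m_snps,
               beta_direct_cog = 0, beta_direct_noncog = 0,
               offspring_per_family = 2, dz_fraction = 0.5,
               adoption_fraction = 0.2, pgs_precision = 1, seed = seed)
  do.call(sim_scenario, utils::modifyList(args, list(...)))
}

# direct effects only, perfect score
direct_scenario <- function(n_families = 2000, m_snps = 200, seed = 102,
                            ...) {
  args <- list(n_families = n_families, m_snps = m_snps,
               beta_direct_cog = 0.15, beta_direct_noncog = 0.15,
               offspring_per_family = 2, dz_fraction = 0.5,
               adoption_fraction = 0.2, pgs_precision = 1, seed = seed)
  do.call(sim_scenario, utils::modifyList(args, list(...)))
}

null_cohort <- function() {
  cached("null2000", simulate_cohort(null_scenario()))
}

direct_cohort <- function() {
  cached("direct2000", simulate_cohort(direct_scenario()))
}

quiet_score_table <- function(cohort, ...) {
  suppressMessages(score_table(cohort, ...))
}

quiet_fit <- function(...) suppressMessages(suppressWarnings(fit_design(...)))
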