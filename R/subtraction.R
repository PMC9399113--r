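# Simplified per-SNP GWAS-by-subtraction: the triangular path algebra that
# maps observed educational-attainment (EA) and cognitive-performance (CP)
# SNP effects onto two independent latent constructs, Cog (shared with CP)
# and NonCog (the residual EA genetic variance after removing CP).

#' Default path loadings for the two-latent-factor model
#'
#' CP loads on Cog only; EA loads on both Cog and NonCog. The defaults are
#' package choices (configurable), set so the Cog-shared and residual paths
#' contribute comparable EA variance.
#'
#' @param cp_cog,ea_cog,ea_noncog path coefficients; `cp_cog` and
#'   `ea_noncog` must be non-zero for identifiability.
#' @return named numeric vector of class `subtraction_loadings`.
#' @export
subtraction_loadings <- function(cp_cog = 1, ea_cog = 0.7, ea_noncog = 0.7) {
  if (cp_cog == 0 || ea_noncog == 0) {
    stop_param("identifiability requires `cp_cog` != 0 and `ea_noncog` != 0")
  }
  structure(c(cp_cog = cp_cog, ea_cog = ea_cog, ea_noncog = ea_noncog),
            class = "subtraction_loadings")
}

#' Solve per-SNP Cog and NonCog effects from EA and CP effects
#'
#' Exact triangular solve of the path model
#' `beta_CP = cp_cog * b_Cog` and
#' `beta_EA = ea_cog * b_Cog + ea_noncog * b_NonCog`:
#' `b_Cog = beta_CP / cp_cog`,
#' `b_NonCog = (beta_EA - ea_cog * b_Cog) / ea_noncog`.
#' The solver is linear, so scaling the inputs scales the solution.
#'
#' @param beta_ea,beta_cp aligned per-SNP observed effect vectors.
#' @param loadings a [subtraction_loadings()] vector.
#' @return data.frame with `b_cog`, `b_noncog`.
#' @examples
#' solve_subtraction(0.3, 0.2, subtraction_loadings(1, 0.5, 1))
#' @export
solve_subtraction <- function(beta_ea, beta_cp,
                              loadings = subtraction_loadings()) {
  if (length(beta_ea) != length(beta_cp)) {
    stop_param("`beta_ea` and `beta_cp` must be aligned vectors")
  }
  if (loadings[["cp_cog"]] == 0 || loadings[["ea_noncog"]] == 0) {
    stop_param("zero loading: model not identifiable")
  }
  b_cog <- beta_cp / loadings[["cp_cog"]]
  b_noncog <- (beta_ea - loadings[["ea_cog"]] * b_cog) /
    loadings[["ea_noncog"]]
  data.frame(b_cog = b_cog, b_noncog = b_noncog)
}

#' Simulate EA/CP summary statistics consistent with the path model
#'
#' Observed effects are the model-implied values plus independent Gaussian
#' noise with the stated SE. `se = 0` reproduces the model identities
#' exactly, so the solver recovers the true effects.
#'
#' @param b_cog,b_noncog true per-SNP latent effects.
#' @param loadings a [subtraction_loadings()] vector.
#' @param se sampling SE of the observed effects (>= 0; scalar or
#'   length-2 vector for EA and CP).
#' @param seed integer seed.
#' @return data.frame with `beta_ea`, `beta_cp`, `se_ea`, `se_cp`.
#' @export
simulate_sumstats <- function(b_cog, b_noncog,
                              loadings = subtraction_loadings(),
                              se = 0, seed = 1) {
  if (any(se < 0)) stop_param("`se` must be >= 0")
  se <- rep_len(se, 2)
  m <- length(b_cog)
  stopifnot(length(b_noncog) == m)
  set.seed(seed)
  beta_cp <- loadings[["cp_cog"]] * b_cog + stats::rnorm(m, 0, se[2])
  beta_ea <- loadings[["ea_cog"]] * b_cog +
    loadings[["ea_noncog"]] * b_noncog + stats::rnorm(m, 0, se[1])
  data.frame(beta_ea = beta_ea, beta_cp = beta_cp,
             se_ea = se[1], se_cp = se[2])
}

#' Convert solved subtraction effects into a PGS weight table
#'
#' @param snp SNP ids.
#' @param solved output of [solve_subtraction()].
#' @param effect_allele counted allele (recycled).
#' @return a weight table compatible with [compute_pgs()].
#' @export
subtraction_weights <- function(snp, solved, effect_allele = "A") {
  data.frame(snp = snp, effect_allele = rep_len(effect_allele, length(snp)),
             weight_cog = solved$b_cog, weight_noncog = solved$b_noncog,
             provenance = "true", stringsAsFactors = FALSE)
}
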