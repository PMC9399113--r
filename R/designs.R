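# The three family-based designs (sibling within/between, adoption contrast,
# trio transmitted/non-transmitted) and the sibling-effect sensitivity models.
# All fits are plain OLS with the covariate set sex, age, sex x age, optional
# ancestry PCs -- mirroring standard cohort practice.

#' Ordinary least squares with named-column diagnostics
#'
#' Fits `y ~ predictors + covariates` with an intercept. Constant covariate
#' columns are dropped with a message (predictors are not); a rank-deficient
#' fit raises an error naming the collinear columns.
#'
#' @param y numeric outcome.
#' @param predictors data.frame of focal predictors.
#' @param covariates optional data.frame of covariates.
#' @return list with `coef`, `se`, `vcov`, `n`, `residuals`, `fit` (the lm).
#' @examples
#' f <- fit_ols(c(1, 2, 3), data.frame(x = c(0, 1, 2)))
#' f$coef
#' @export
fit_ols <- function(y, predictors, covariates = NULL) {
  predictors <- as.data.frame(predictors)
  dat <- predictors
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    const <- vapply(covariates, function(x) length(unique(x)) <= 1L,
                    logical(1))
    if (any(const)) {
      message("dropping constant covariate(s): ",
              paste(names(covariates)[const], collapse = ", "))
      covariates <- covariates[, !const, drop = FALSE]
    }
    if (ncol(covariates) > 0) dat <- cbind(dat, covariates)
  }
  dat$.y <- y
  if (nrow(dat) <= ncol(dat)) {
    stop("need more observations than parameters", call. = FALSE)
  }
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular fit; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  list(coef = cf, se = sqrt(diag(stats::vcov(fit))), vcov = stats::vcov(fit),
       n = length(y), residuals = stats::resid(fit), fit = fit)
}

# Expand a covariate specification into a numeric covariate frame.
# "sex" -> indicator, "age" -> years, sex x age added when both present;
# other names are taken as numeric columns of `tab` (e.g. pc1..pcK).
build_covars <- function(tab, covar_cols) {
  if (is.null(covar_cols) || length(covar_cols) == 0) return(NULL)
  out <- list()
  if ("sex" %in% covar_cols) out$sex <- as.numeric(tab$sex == "F")
  if ("age" %in% covar_cols) out$age <- tab$age
  if (all(c("sex", "age") %in% covar_cols)) out$sexage <- out$sex * out$age
  for (cn in setdiff(covar_cols, c("sex", "age"))) {
    if (!cn %in% names(tab)) {
      stop_param("unknown covariate column `", cn, "`")
    }
    out[[cn]] <- tab[[cn]]
  }
  as.data.frame(out)
}

new_estimate_set <- function(design, coefficients, derived, n_persons,
                             n_families, extra = list()) {
  structure(c(list(design = design, coefficients = coefficients,
                   derived = derived, n_persons = n_persons,
                   n_families = n_families), extra),
            class = "estimate_set")
}

#' @export
print.estimate_set <- function(x, digits = 3, ...) {
  cat(sprintf("<estimate_set: %s design; %d persons, %d families>\n",
              x$design, x$n_persons, x$n_families))
  print(format(x$derived, digits = digits), ...)
  invisible(x)
}

derived_row <- function(construct, population, direct, indirect) {
  data.frame(construct = construct, population = population,
             direct = direct, indirect = indirect,
             ratio_ind_pop = indirect / population,
             ratio_ind_dir = indirect / direct,
             stringsAsFactors = FALSE)
}

#' Sibling design: within/between and population regressions
#'
#' Fits the within + between-family regression (both constructs jointly) and
#' the population regression on the same rows, with identical covariates.
#' The direct effect is the within-family coefficient; the indirect effect
#' is population minus within, exactly as computed.
#'
#' @param tab a sibling-standardized score table
#'   ([standardize_for_design()] with `design = "sibling"`); a raw table is
#'   standardized on the fly.
#' @param covar_cols covariate specification for [build_covars()]
#'   (default sex, age, and their interaction).
#' @return an `estimate_set` with per-construct `population`, `direct`
#'   (= within), `between`, `indirect` and naive SEs (the family-resampled
#'   bootstrap is the authoritative uncertainty; see [bootstrap_design()]).
#' @export
sibling_design <- function(tab, covar_cols = c("sex", "age")) {
  if (!"pgs_cog_dev" %in% names(tab)) {
    tab <- standardize_for_design(tab, "sibling")
  }
  y <- zscale(tab$y, "outcome")
  covars <- build_covars(tab, covar_cols)
  eq1 <- fit_ols(y, tab[, c("pgs_cog_dev", "pgs_cog_fam",
                            "pgs_noncog_dev", "pgs_noncog_fam")], covars)
  eq2 <- fit_ols(y, tab[, c("pgs_cog_z", "pgs_noncog_z")], covars)

  rows <- list()
  cfs <- list()
  for (cc in c("cog", "noncog")) {
    within <- unname(eq1$coef[paste0("pgs_", cc, "_dev")])
    between <- unname(eq1$coef[paste0("pgs_", cc, "_fam")])
    population <- unname(eq2$coef[paste0("pgs_", cc, "_z")])
    indirect <- population - within
    rows[[cc]] <- derived_row(cc, population, within, indirect)
    cfs[[cc]] <- data.frame(
      construct = cc,
      term = c("within", "between", "population", "indirect"),
      estimate = c(within, between, population, indirect),
      se = c(unname(eq1$se[paste0("pgs_", cc, "_dev")]),
             unname(eq1$se[paste0("pgs_", cc, "_fam")]),
             unname(eq2$se[paste0("pgs_", cc, "_z")]),
             sqrt(eq1$se[paste0("pgs_", cc, "_dev")]^2 +
                    eq2$se[paste0("pgs_", cc, "_z")]^2)),
      stringsAsFactors = FALSE
    )
  }
  new_estimate_set("sibling", do.call(rbind, cfs), do.call(rbind, rows),
                   n_persons = nrow(tab),
                   n_families = length(unique(tab$family_id)))
}

#' Adoption design: adoptee vs non-adopted contrast
#'
#' Fits the population-form regression separately in the adoptee and
#' non-adopted groups (scores scaled per group). The population effect is
#' the non-adopted coefficient, the direct effect the adoptee coefficient,
#' and the indirect effect their difference, exactly.
#'
#' @param tab an adoption-standardized score table (raw tables are
#'   standardized on the fly).
#' @param covar_cols covariate specification, as in [sibling_design()].
#' @return an `estimate_set`; warns when a group has fewer than 10
#'   observations per parameter.
#' @export
adoption_design <- function(tab, covar_cols = c("sex", "age")) {
  if (!"group" %in% names(tab)) {
    tab <- standardize_for_design(tab, "adoption")
  }
  if (!all(c("adopted", "nonadopted") %in% tab$group)) {
    stop("both adoptee and non-adopted groups must be non-empty",
         call. = FALSE)
  }
  y <- zscale(tab$y, "outcome")
  fits <- list()
  for (g in c("adopted", "nonadopted")) {
    sel <- tab$group == g
    sub <- tab[sel, ]
    covars <- build_covars(sub, covar_cols)
    p <- 2 + 1 + if (is.null(covars)) 0 else ncol(covars)
    if (sum(sel) < 10 * p) {
      warning(sprintf("%s group has n = %d < 10 parameters per term",
                      g, sum(sel)), call. = FALSE)
    }
    fits[[g]] <- fit_ols(y[sel], sub[, c("pgs_cog_z", "pgs_noncog_z")],
                         covars)
  }
  rows <- list()
  cfs <- list()
  for (cc in c("cog", "noncog")) {
    key <- paste0("pgs_", cc, "_z")
    population <- unname(fits$nonadopted$coef[key])
    direct <- unname(fits$adopted$coef[key])
    indirect <- population - direct
    rows[[cc]] <- derived_row(cc, population, direct, indirect)
    cfs[[cc]] <- data.frame(
      construct = cc,
      term = c("population", "direct", "indirect"),
      estimate = c(population, direct, indirect),
      se = c(unname(fits$nonadopted$se[key]), unname(fits$adopted$se[key]),
             sqrt(fits$nonadopted$se[key]^2 + fits$adopted$se[key]^2)),
      stringsAsFactors = FALSE
    )
  }
  new_estimate_set("adoption", do.call(rbind, cfs), do.call(rbind, rows),
                   n_persons = nrow(tab),
                   n_families = length(unique(tab$family_id)),
                   extra = list(n_adopted = sum(tab$group == "adopted")))
}

#' Trio design: transmitted and non-transmitted composites
#'
#' Single regression of the outcome on the transmitted and non-transmitted
#' composites for both constructs. The indirect effect is the
#' non-transmitted coefficient; the direct effect is transmitted minus
#' non-transmitted, exactly; the population analogue is the transmitted
#' coefficient.
#'
#' @param tab a trio-standardized score table ([build_trio_scores()]); raw
#'   tables are standardized on the fly.
#' @param covar_cols covariate specification, as in [sibling_design()].
#' @return an `estimate_set`.
#' @export
trio_design <- function(tab, covar_cols = c("sex", "age")) {
  if (!"pgs_t_cog" %in% names(tab)) {
    tab <- build_trio_scores(tab)
  }
  y <- zscale(tab$y, "outcome")
  covars <- build_covars(tab, covar_cols)
  fit <- fit_ols(y, tab[, c("pgs_t_cog", "pgs_t_noncog",
                            "pgs_nt_cog", "pgs_nt_noncog")], covars)
  rows <- list()
  cfs <- list()
  for (cc in c("cog", "noncog")) {
    kt <- paste0("pgs_t_", cc)
    kn <- paste0("pgs_nt_", cc)
    beta_t <- unname(fit$coef[kt])
    beta_nt <- unname(fit$coef[kn])
    direct <- beta_t - beta_nt
    se_dir <- sqrt(fit$vcov[kt, kt] + fit$vcov[kn, kn] -
                     2 * fit$vcov[kt, kn])
    rows[[cc]] <- derived_row(cc, beta_t, direct, beta_nt)
    cfs[[cc]] <- data.frame(
      construct = cc,
      term = c("beta_t", "beta_nt", "direct"),
      estimate = c(beta_t, beta_nt, direct),
      se = c(unname(fit$se[kt]), unname(fit$se[kn]), se_dir),
      stringsAsFactors = FALSE
    )
  }
  new_estimate_set("trio", do.call(rbind, cfs), do.call(rbind, rows),
                   n_persons = nrow(tab),
                   n_families = length(unique(tab$family_id)))
}

#' Sibling-effect model on genotyped quads
#'
#' Extends the trio regression with the co-sibling's own PGS (both
#' constructs), on DZ pairs with both parents genotyped. A non-zero
#' co-sibling coefficient indicates sibling indirect genetic effects.
#'
#' @param tab raw score table; restricted internally to DZ offspring with a
#'   co-sibling and both parental scores.
#' @param covar_cols covariate specification.
#' @return an `estimate_set` with `beta_sibling` rows in `coefficients`.
#' @export
sibling_effects_model <- function(tab, covar_cols = c("sex", "age")) {
  off <- tab[tab$role == "offspring" & tab$zygosity == "DZ" &
               !is.na(tab$pgs_sib_cog), ]
  if (nrow(off) == 0) {
    stop("no DZ offspring with a genotyped co-sibling", call. = FALSE)
  }
  trio <- build_trio_scores(off)
  for (cc in c("cog", "noncog")) {
    trio[[paste0("pgs_sib_", cc, "_z")]] <-
      zscale(trio[[paste0("pgs_sib_", cc)]], "co-sibling PGS")
  }
  y <- zscale(trio$y, "outcome")
  covars <- build_covars(trio, covar_cols)
  fit <- fit_ols(y, trio[, c("pgs_t_cog", "pgs_t_noncog",
                             "pgs_nt_cog", "pgs_nt_noncog",
                             "pgs_sib_cog_z", "pgs_sib_noncog_z")], covars)
  rows <- list()
  cfs <- list()
  for (cc in c("cog", "noncog")) {
    kt <- paste0("pgs_t_", cc)
    kn <- paste0("pgs_nt_", cc)
    ks <- paste0("pgs_sib_", cc, "_z")
    beta_t <- unname(fit$coef[kt])
    beta_nt <- unname(fit$coef[kn])
    rows[[cc]] <- derived_row(cc, beta_t, beta_t - beta_nt, beta_nt)
    cfs[[cc]] <- data.frame(
      construct = cc,
      term = c("beta_t", "beta_nt", "beta_sibling"),
      estimate = c(beta_t, beta_nt, unname(fit$coef[ks])),
      se = c(unname(fit$se[kt]), unname(fit$se[kn]), unname(fit$se[ks])),
      stringsAsFactors = FALSE
    )
  }
  new_estimate_set("quad", do.call(rbind, cfs), do.call(rbind, rows),
                   n_persons = nrow(trio),
                   n_families = length(unique(trio$family_id)))
}

#' MZ/DZ contrast of population PGS effects
#'
#' Fits the population regression in a subset of MZ twins and a subset of DZ
#' twins (one individual per pair; scores scaled within each subset) and
#' reports the per-construct difference as a pooled-SE Z statistic. Under
#' sibling indirect effects the MZ coefficient is inflated relative to DZ.
#'
#' @param tab raw score table.
#' @param covar_cols covariate specification.
#' @return list with `mz`, `dz` (`estimate_set`-like fits) and `contrast`
#'   (data.frame construct, beta_mz, beta_dz, z, p).
#' @export
mzdz_contrast <- function(tab, covar_cols = c("sex", "age")) {
  pick_one <- function(zyg) {
    off <- tab[tab$role == "offspring" & tab$zygosity == zyg, ]
    if (nrow(off) == 0) stop("empty ", zyg, " subset", call. = FALSE)
    off[!duplicated(off$family_id), ]
  }
  fit_pop <- function(off) {
    for (cc in c("cog", "noncog")) {
      off[[paste0("pgs_", cc, "_z")]] <-
        zscale(off[[paste0("pgs_", cc)]], "PGS")
    }
    y <- zscale(off$y, "outcome")
    fit_ols(y, off[, c("pgs_cog_z", "pgs_noncog_z")],
            build_covars(off, covar_cols))
  }
  fmz <- fit_pop(pick_one("MZ"))
  fdz <- fit_pop(pick_one("DZ"))
  contrast <- do.call(rbind, lapply(c("cog", "noncog"), function(cc) {
    key <- paste0("pgs_", cc, "_z")
    d <- unname(fmz$coef[key] - fdz$coef[key])
    se <- sqrt(fmz$se[key]^2 + fdz$se[key]^2)
    z <- unname(d / se)
    data.frame(construct = cc, beta_mz = unname(fmz$coef[key]),
               beta_dz = unname(fdz$coef[key]), diff = d, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  list(mz = fmz, dz = fdz, contrast = contrast)
}

#' Number-of-siblings moderation of the population PGS effect
#'
#' Augments the population regression with PGS x sibship-size interactions,
#' fitted separately for biological (non-adopted) offspring and adoptees
#' (whose rearing siblings are genetically unrelated, so a sibling genetic
#' effect cannot drive the interaction there). Reports both interaction
#' coefficients and their contrast per construct.
#'
#' @param tab raw score table with an `n_sibs` column ([score_table()]).
#' @param covar_cols covariate specification.
#' @return list with `biological`, `adopted` fits (or `NULL` when flagged),
#'   `contrast` data.frame, and `inestimable` flag set when the sibship size
#'   is constant within a group.
#' @export
nsib_moderation <- function(tab, covar_cols = c("sex", "age")) {
  off <- tab[tab$role == "offspring" & !is.na(tab$n_sibs), ]
  fits <- list()
  inest <- FALSE
  for (g in c("biological", "adopted")) {
    sub <- off[if (g == "adopted") off$adopted else !off$adopted, ]
    if (nrow(sub) == 0 || length(unique(sub$n_sibs)) <= 1L) {
      message("sibship size constant in ", g,
              " group: interaction inestimable")
      fits[[g]] <- NULL
      inest <- TRUE
      next
    }
    for (cc in c("cog", "noncog")) {
      sub[[paste0("pgs_", cc, "_z")]] <-
        zscale(sub[[paste0("pgs_", cc)]], "PGS")
    }
    ns <- sub$n_sibs - mean(sub$n_sibs)
    preds <- data.frame(
      pgs_cog_z = sub$pgs_cog_z, pgs_noncog_z = sub$pgs_noncog_z,
      n_sibs_c = ns,
      pgs_cog_x_nsib = sub$pgs_cog_z * ns,
      pgs_noncog_x_nsib = sub$pgs_noncog_z * ns
    )
    fits[[g]] <- fit_ols(zscale(sub$y, "outcome"), preds,
                         build_covars(sub, covar_cols))
  }
  contrast <- NULL
  if (!inest) {
    contrast <- do.call(rbind, lapply(c("cog", "noncog"), function(cc) {
      key <- paste0("pgs_", cc, "_x_nsib")
      d <- unname(fits$biological$coef[key] - fits$adopted$coef[key])
      se <- sqrt(fits$biological$se[key]^2 + fits$adopted$se[key]^2)
      data.frame(construct = cc,
                 interaction_bio = unname(fits$biological$coef[key]),
                 interaction_adopted = unname(fits$adopted$coef[key]),
                 diff = d, z = unname(d / se), stringsAsFactors = FALSE)
    }))
  }
  list(biological = fits$biological, adopted = fits$adopted,
       contrast = contrast, inestimable = inest)
}

#' Fit a family design on a simulated cohort
#'
#' Convenience wrapper: builds the score table, optionally attaches ancestry
#' PCs as covariates, applies the design's standardization, and fits it.
#'
#' @param cohort a `family_cohort`.
#' @param design `"sibling"`, `"adoption"`, `"trio"`, `"quad"`, `"mzdz"`
#'   or `"nsib"`.
#' @param weights `"measured"` (default) or `"true"`.
#' @param n_pcs number of ancestry PCs to include as covariates (0 = none).
#' @param tab optional pre-built raw score table (avoids recomputation).
#' @return an `estimate_set` (or the contrast list for `"mzdz"` / `"nsib"`).
#' @examples
#' sc <- sim_scenario(n_families = 300, m_snps = 100,
#'                    beta_postnatal_cog = 0.1, seed = 2)
#' fit_design(simulate_cohort(sc), "sibling")
#' @export
fit_design <- function(cohort, design = c("sibling", "adoption", "trio",
                                          "quad", "mzdz", "nsib"),
                       weights = "measured", n_pcs = 0, tab = NULL) {
  design <- match.arg(design)
  tab <- tab %||% score_table(cohort, weights)
  covar_cols <- c("sex", "age")
  if (n_pcs > 0) {
    pcs <- cohort_pcs(cohort, K = n_pcs)
    for (k in seq_len(n_pcs)) tab[[paste0("pc", k)]] <- pcs[, k]
    covar_cols <- c(covar_cols, paste0("pc", seq_len(n_pcs)))
  }
  switch(design,
    sibling = sibling_design(standardize_for_design(tab, "sibling"),
                             covar_cols),
    adoption = adoption_design(standardize_for_design(tab, "adoption"),
                               covar_cols),
    trio = trio_design(build_trio_scores(tab), covar_cols),
    quad = sibling_effects_model(tab, covar_cols),
    mzdz = mzdz_contrast(tab, covar_cols),
    nsib = nsib_moderation(tab, covar_cols)
  )
}
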