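# Uncertainty machinery: ordinary nonparametric bootstrap with family-level
# (or two-strata) resampling, bias-corrected normal confidence intervals,
# ratio statistics, Z-tests for contrasts, random-effects meta-analysis, and
# the sibling-ICC / spousal-correlation diagnostics for assortative mating.

design_statistic <- function(design) {
  fitter <- switch(design,
    sibling = sibling_design, adoption = adoption_design,
    trio = trio_design, quad = sibling_effects_model,
    stop_param("unsupported design for bootstrap: ", design)
  )
  function(tab, covar_cols) {
    est <- fitter(tab, covar_cols)
    d <- est$derived
    vals <- c(d$population, d$direct, d$indirect,
              d$ratio_ind_pop, d$ratio_ind_dir)
    names(vals) <- as.vector(outer(
      d$construct, c("population", "direct", "indirect",
                     "ratio_ind_pop", "ratio_ind_dir"),
      function(cc, m) paste0(m, "_", cc)))
    vals
  }
}

#' Nonparametric bootstrap for a family design
#'
#' Ordinary nonparametric bootstrap of a design fit. Families are the
#' resampling unit for the sibling, trio and quad designs (keeping sibships
#' and trios intact; the sibling design's two regressions are refit on the
#' same bootstrap sample). For the adoption design, rows are resampled from
#' the adoptee and non-adopted strata separately. Row-level resampling is
#' available via `scheme = "row"`.
#'
#' Confidence intervals are bias-corrected normal intervals,
#' `2 * estimate - mean(draws) +/- z * SE(draws)`, with percentile intervals
#' as an option.
#'
#' @param tab a design-standardized score table (see
#'   [standardize_for_design()]); standardization is done once, as in
#'   row-resampling practice.
#' @param design `"sibling"`, `"adoption"`, `"trio"` or `"quad"`.
#' @param B number of replications (>= 100; the reference analysis uses
#'   10,000).
#' @param seed integer seed.
#' @param covar_cols covariate specification (see [sibling_design()]).
#' @param scheme `"auto"` (family resampling; two-strata for adoption) or
#'   `"row"`.
#' @param level confidence level.
#' @param ci `"bc-normal"` (default) or `"percentile"`.
#' @return a `bootstrap_result`: `point`, `se`, `ci` (data.frame), `draws`
#'   (B x statistics), `B`, `B_failed`, `scheme`, `seed`.
#' @export
bootstrap_design <- function(tab, design, B = 10000, seed = 1,
                             covar_cols = c("sex", "age"),
                             scheme = c("auto", "row"), level = 0.95,
                             ci = c("bc-normal", "percentile")) {
  scheme <- match.arg(scheme)
  ci <- match.arg(ci)
  if (B < 100) stop_param("`B` must be >= 100")
  stat <- design_statistic(design)
  point <- stat(tab, covar_cols)

  resample <- if (scheme == "row") {
    if (design == "adoption") {
      strata <- split(seq_len(nrow(tab)), tab$group)
      function() unlist(lapply(strata, function(ix)
        sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
    } else {
      function() sample.int(nrow(tab), replace = TRUE)
    }
  } else if (design == "adoption") {
    # the reference procedure: draw from the two groups separately
    strata <- split(seq_len(nrow(tab)), tab$group)
    function() unlist(lapply(strata, function(ix)
      sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
  } else {
    fam_rows <- split(seq_len(nrow(tab)), tab$family_id)
    nf <- length(fam_rows)
    function() unlist(fam_rows[sample.int(nf, replace = TRUE)],
                      use.names = FALSE)
  }

  set.seed(seed)
  draws <- matrix(NA_real_, B, length(point),
                  dimnames = list(NULL, names(point)))
  failed <- 0L
  for (b in seq_len(B)) {
    rows <- resample()
    v <- tryCatch(suppressMessages(stat(tab[rows, ], covar_cols)),
                  error = function(e) NULL)
    if (is.null(v)) failed <- failed + 1L else draws[b, ] <- v
  }
  if (failed > 0.01 * B) {
    stop(sprintf("bootstrap failed in %d/%d replicates", failed, B),
         call. = FALSE)
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  se <- apply(draws, 2, stats::sd)
  q <- stats::qnorm(1 - (1 - level) / 2)
  if (ci == "bc-normal") {
    center <- 2 * point - colMeans(draws)
    lower <- center - q * se
    upper <- center + q * se
  } else {
    lower <- apply(draws, 2, stats::quantile, (1 - level) / 2)
    upper <- apply(draws, 2, stats::quantile, 1 - (1 - level) / 2)
  }
  structure(list(
    point = point, se = se,
    ci = data.frame(statistic = names(point), estimate = unname(point),
                    se = unname(se), lower = unname(lower),
                    upper = unname(upper), stringsAsFactors = FALSE),
    draws = draws, B = B, B_failed = failed,
    scheme = if (scheme == "row") "row" else
      if (design == "adoption") "two-strata" else "family",
    seed = seed, level = level, ci_type = ci
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, digits = 3, ...) {
  cat(sprintf("<bootstrap_result: B = %d (%d failed), %s resampling, %s CI>\n",
              x$B, x$B_failed, x$scheme, x$ci_type))
  print(format(x$ci, digits = digits), ...)
  invisible(x)
}

#' Ratio of indirect to population and to direct effects
#'
#' Computes `indirect / population` and (when `direct` is supplied)
#' `indirect / direct`, optionally propagating uncertainty through paired
#' bootstrap draws. A denominator below `tol` in absolute value flags the
#' ratio unstable and suppresses its CI.
#'
#' @param indirect,population,direct point estimates (scalars).
#' @param draws optional matrix of paired bootstrap draws with columns named
#'   `indirect`, `population` (and `direct`).
#' @param tol denominator tolerance.
#' @param level confidence level.
#' @return data.frame with one row per ratio: `ratio`, `value`, `percent`,
#'   `se`, `lower`, `upper`, `unstable`.
#' @examples
#' ratio_stats(indirect = 0.08, population = 0.22)  # 36% of the population
#' @export
ratio_stats <- function(indirect, population, direct = NULL, draws = NULL,
                        tol = 1e-8, level = 0.95) {
  one <- function(name, num, den, dnum, dden) {
    unstable <- abs(den) < tol
    val <- if (unstable) NA_real_ else num / den
    se <- lower <- upper <- NA_real_
    if (!unstable && !is.null(dnum)) {
      ok <- abs(dden) >= tol
      r <- dnum[ok] / dden[ok]
      se <- stats::sd(r)
      q <- stats::qnorm(1 - (1 - level) / 2)
      center <- 2 * val - mean(r)
      lower <- center - q * se
      upper <- center + q * se
    }
    data.frame(ratio = name, value = val, percent = 100 * val, se = se,
               lower = lower, upper = upper, unstable = unstable,
               stringsAsFactors = FALSE)
  }
  dcol <- function(name) if (is.null(draws)) NULL else draws[, name]
  out <- one("indirect/population", indirect, population,
             dcol("indirect"), dcol("population"))
  if (!is.null(direct)) {
    out <- rbind(out, one("indirect/direct", indirect, direct,
                          dcol("indirect"), dcol("direct")))
  }
  out
}

#' Z-test for the difference of two estimates
#'
#' `Z = (A - B) / SE(A - B)`, with the SE taken from paired bootstrap draws
#' of the difference when available, else from independent SEs in
#' quadrature. Two-sided p-value.
#'
#' @param a,b point estimates.
#' @param se_a,se_b standard errors (used when draws are absent).
#' @param draws_a,draws_b paired bootstrap draws of the two estimates.
#' @return list with `diff`, `se`, `z`, `p`.
#' @export
z_difference <- function(a, b, se_a = NULL, se_b = NULL,
                         draws_a = NULL, draws_b = NULL) {
  d <- a - b
  se <- if (!is.null(draws_a) && !is.null(draws_b)) {
    stats::sd(draws_a - draws_b)
  } else {
    sqrt(se_a^2 + se_b^2)
  }
  if (!is.finite(se) || se == 0) {
    if (d == 0) return(list(diff = 0, se = se, z = 0, p = 1))
    stop("zero standard error for a non-zero difference", call. = FALSE)
  }
  z <- d / se
  list(diff = d, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Random-effects meta-analysis of design estimates
#'
#' Pools estimates with inverse-variance random-effects REML. When more than
#' one design contributes, the design is a random intercept factor (two-level
#' model via `metafor::rma.mv`); within a single design the model collapses
#' to a standard random-effects meta-analysis. `method = "FE"` gives the
#' fixed-effect (no heterogeneity) pool.
#'
#' @param estimates data.frame with columns `estimate`, `se`, and optionally
#'   `design` (grouping factor) and `id`.
#' @param method `"REML"` (default) or `"FE"`.
#' @param level confidence level.
#' @return a `meta_result`: `pooled`, `se`, `lower`, `upper`, `tau2`
#'   (estimate-level heterogeneity variance), `tau2_design` (design random
#'   intercept variance, `NA` when not modelled), `k`, `weights`, `fit`.
#' @examples
#' meta_analyze(data.frame(estimate = c(0, 0.2), se = c(0.05, 0.05)),
#'              method = "FE")$pooled
#' @export
meta_analyze <- function(estimates, method = c("REML", "FE"), level = 0.95) {
  method <- match.arg(method)
  stopifnot(all(c("estimate", "se") %in% names(estimates)))
  if (any(estimates$se <= 0)) stop_param("all SEs must be > 0")
  k <- nrow(estimates)
  if (k == 1) {
    warning("single estimate: returning it unchanged", call. = FALSE)
    q <- stats::qnorm(1 - (1 - level) / 2)
    return(structure(list(
      pooled = estimates$estimate, se = estimates$se,
      lower = estimates$estimate - q * estimates$se,
      upper = estimates$estimate + q * estimates$se,
      tau2 = 0, tau2_design = NA_real_, k = 1L, weights = 1, fit = NULL
    ), class = "meta_result"))
  }
  estimates$id <- estimates$id %||% seq_len(k)
  multi_design <- "design" %in% names(estimates) &&
    length(unique(estimates$design)) > 1
  if (method == "FE") {
    fit <- metafor::rma(yi = estimates$estimate, sei = estimates$se,
                        method = "FE", level = 100 * level)
    tau2 <- 0
    tau2_design <- NA_real_
    w <- metafor::weights.rma.uni(fit)
  } else if (multi_design) {
    fit <- metafor::rma.mv(yi = estimate, V = se^2,
                           random = list(~ 1 | design, ~ 1 | id),
                           data = estimates, method = "REML",
                           level = 100 * level)
    tau2_design <- fit$sigma2[1]
    tau2 <- fit$sigma2[2]
    w <- 1 / (estimates$se^2 + tau2 + tau2_design)
  } else {
    fit <- metafor::rma(yi = estimates$estimate, sei = estimates$se,
                        method = "REML", level = 100 * level)
    tau2 <- fit$tau2
    tau2_design <- NA_real_
    w <- metafor::weights.rma.uni(fit)
  }
  structure(list(
    pooled = as.numeric(fit$beta), se = fit$se,
    lower = fit$ci.lb, upper = fit$ci.ub,
    tau2 = tau2, tau2_design = tau2_design, k = k,
    weights = as.numeric(w), fit = fit
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 3, ...) {
  cat(sprintf("<meta_result: k = %d>\n  pooled %s (SE %s), CI [%s, %s]\n",
              x$k, format(x$pooled, digits = digits),
              format(x$se, digits = digits),
              format(x$lower, digits = digits),
              format(x$upper, digits = digits)))
  cat(sprintf("  tau2 = %s  tau2(design) = %s\n",
              format(x$tau2, digits = digits),
              format(x$tau2_design, digits = digits)))
  invisible(x)
}

#' Sibling intraclass and spousal correlations of polygenic scores
#'
#' Diagnostics for assortative mating and stratification: under random
#' mating and no structure, the sibling PGS intraclass correlation (double
#' entry) is 0.5 and the spousal PGS correlation is 0. The ICC is computed
#' as the Pearson correlation over all ordered within-family sibling pairs
#' (double entry); CIs use the Fisher transform on the number of unordered
#' pairs / couples.
#'
#' @param tab a raw score table from [score_table()].
#' @param min_pairs minimum number of sibling pairs and couples.
#' @param level confidence level.
#' @return data.frame: `statistic` (`sibling_icc` / `spousal_r`),
#'   `construct`, `value`, `lower`, `upper`, `n_pairs`.
#' @export
pgs_correlation_diagnostics <- function(tab, min_pairs = 30, level = 0.95) {
  off <- tab[tab$role == "offspring" & !tab$adopted, ]
  fam_n <- table(off$family_id)
  off <- off[off$family_id %in% names(fam_n)[fam_n >= 2], ]
  pairs <- merge(off[, c("family_id", "person_id", "pgs_cog", "pgs_noncog")],
                 off[, c("family_id", "person_id", "pgs_cog", "pgs_noncog")],
                 by = "family_id", suffixes = c("_1", "_2"))
  pairs <- pairs[pairs$person_id_1 != pairs$person_id_2, ]

  fathers <- tab[tab$role == "father", ]
  mothers <- tab[tab$role == "mother", ]
  couples <- merge(fathers[, c("family_id", "pgs_cog", "pgs_noncog")],
                   mothers[, c("family_id", "pgs_cog", "pgs_noncog")],
                   by = "family_id", suffixes = c("_f", "_m"))

  n_sib_pairs <- nrow(pairs) / 2
  if (n_sib_pairs < min_pairs || nrow(couples) < min_pairs) {
    stop(sprintf("too few pairs (%d sibling pairs, %d couples; need %d)",
                 n_sib_pairs, nrow(couples), min_pairs), call. = FALSE)
  }
  out <- list()
  for (cc in c("cog", "noncog")) {
    icc <- stats::cor(pairs[[paste0("pgs_", cc, "_1")]],
                      pairs[[paste0("pgs_", cc, "_2")]])
    ci1 <- fisher_ci(icc, n_sib_pairs, level)
    r <- stats::cor(couples[[paste0("pgs_", cc, "_f")]],
                    couples[[paste0("pgs_", cc, "_m")]])
    ci2 <- fisher_ci(r, nrow(couples), level)
    out[[cc]] <- data.frame(
      statistic = c("sibling_icc", "spousal_r"), construct = cc,
      value = c(icc, r), lower = c(ci1[1], ci2[1]),
      upper = c(ci1[2], ci2[2]),
      n_pairs = c(n_sib_pairs, nrow(couples)), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
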