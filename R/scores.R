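# Polygenic scores: own, transmitted / non-transmitted, mid-parent, family
# mean and within-family deviation, with the design-specific standardization
# rules used by the three family designs.

#' Compute polygenic scores from a dosage matrix and a weight table
#'
#' Score = sum over SNPs of dosage times weight, per construct. The weight
#' table defines the counted (effect) allele; if `counted` alleles are given
#' for the dosage matrix, mismatching SNPs are flipped (`2 - dosage`).
#'
#' @param dos dosage matrix (persons x SNPs, colnames = SNP ids).
#' @param weights weight table (`snp`, `effect_allele`, `weight_cog`,
#'   `weight_noncog`).
#' @param counted optional named character vector giving the allele counted
#'   by `dos` per SNP; defaults to the weights' effect allele.
#' @param missing `"error"` (default) or `"mean"` to mean-impute missing
#'   dosages per SNP.
#' @return numeric matrix persons x constructs (`cog`, `noncog`).
#' @examples
#' dos <- rbind(a = c(s1 = 0, s2 = 1, s3 = 2), b = c(2, 0, 1))
#' w <- data.frame(snp = c("s1", "s2", "s3"), effect_allele = "A",
#'                 weight_cog = c(0.5, -1, 0.25),
#'                 weight_noncog = 0)
#' compute_pgs(dos, w)
#' @export
compute_pgs <- function(dos, weights, counted = NULL,
                        missing = c("error", "mean")) {
  missing <- match.arg(missing)
  stopifnot(is.matrix(dos))
  idx <- match(weights$snp, colnames(dos))
  if (anyNA(idx)) {
    stop("SNP mismatch: weights name SNPs absent from the dosage matrix: ",
         paste(utils::head(weights$snp[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  d <- dos[, idx, drop = FALSE]
  if (!is.null(counted)) {
    cnt <- counted[weights$snp]
    if (anyNA(cnt)) {
      stop("unknown counted allele for some SNPs", call. = FALSE)
    }
    flip <- cnt != weights$effect_allele
    if (any(flip)) d[, flip] <- 2 - d[, flip]
  }
  if (anyNA(d)) {
    if (missing == "error") {
      stop("missing dosages; set missing = \"mean\" to impute", call. = FALSE)
    }
    for (j in which(colSums(is.na(d)) > 0)) {
      d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
    }
  }
  out <- d %*% cbind(cog = weights$weight_cog, noncog = weights$weight_noncog)
  rownames(out) <- rownames(dos)
  out
}

#' Transmitted and non-transmitted parental scores
#'
#' For each offspring, the transmitted paternal (maternal) score is the
#' weighted sum of the alleles the father (mother) transmitted; the
#' non-transmitted score is the weighted sum of the complementary alleles.
#' On the raw scale these satisfy, exactly:
#' transmitted paternal + transmitted maternal = offspring's own score, and
#' transmitted + non-transmitted = the parent's own score (per parent).
#'
#' @param cohort a `family_cohort` with transmission flags.
#' @param weights weight table (defaults to the cohort's measured weights,
#'   falling back to the true weights).
#' @return data.frame keyed by `person_id` (offspring) with columns
#'   `pgs_t_pat_*`, `pgs_t_mat_*`, `pgs_nt_pat_*`, `pgs_nt_mat_*` for
#'   `* = cog, noncog`.
#' @export
haplotype_scores <- function(cohort, weights = NULL) {
  stopifnot(inherits(cohort, "family_cohort"))
  if (is.null(cohort$trans_pat)) {
    stop("transmission flags missing from cohort", call. = FALSE)
  }
  weights <- weights %||% cohort$weights_meas %||% cohort$weights_true
  per <- cohort$persons
  off <- per[per$role == "offspring", ]
  W <- cbind(cog = weights$weight_cog, noncog = weights$weight_noncog)
  stopifnot(identical(weights$snp, colnames(cohort$hap1)))

  t_pat <- cohort$hap1[as.character(off$person_id), , drop = FALSE]
  t_mat <- cohort$hap2[as.character(off$person_id), , drop = FALSE]
  dos_f <- dosages(cohort, off$father_id)
  dos_m <- dosages(cohort, off$mother_id)
  nt_pat <- dos_f - t_pat
  nt_mat <- dos_m - t_mat

  s <- function(x) x %*% W
  out <- data.frame(person_id = off$person_id)
  for (cc in c("cog", "noncog")) {
    out[[paste0("pgs_t_pat_", cc)]] <- s(t_pat)[, cc]
    out[[paste0("pgs_t_mat_", cc)]] <- s(t_mat)[, cc]
    out[[paste0("pgs_nt_pat_", cc)]] <- s(nt_pat)[, cc]
    out[[paste0("pgs_nt_mat_", cc)]] <- s(nt_mat)[, cc]
  }
  out
}

#' Build the per-person score table for a cohort
#'
#' Combines the person table with own PGS for everyone, transmitted /
#' non-transmitted parental scores for offspring, the mean rearing
#' co-sibling PGS, and the rearing sibship size.
#'
#' @param cohort a `family_cohort`.
#' @param weights `"measured"` (default), `"true"`, or a weight table.
#' @return data.frame (one row per person); scale tag attribute `"raw"`.
#' @export
score_table <- function(cohort, weights = c("measured", "true")) {
  stopifnot(inherits(cohort, "family_cohort"))
  if (is.character(weights)) {
    weights <- match.arg(weights)
    weights <- switch(weights, measured = cohort$weights_meas %||%
                        cohort$weights_true, true = cohort$weights_true)
  }
  per <- cohort$persons
  own <- compute_pgs(dosages(cohort), weights)
  tab <- per
  tab$pgs_cog <- own[, "cog"]
  tab$pgs_noncog <- own[, "noncog"]

  hs <- haplotype_scores(cohort, weights)
  tab <- merge(tab, hs, by = "person_id", all.x = TRUE, sort = FALSE)
  tab <- tab[order(tab$person_id), ]

  # rearing co-sibling mean PGS and sibship size (offspring only)
  off <- tab$role == "offspring"
  tab$n_sibs <- NA_integer_
  tab$pgs_sib_cog <- NA_real_
  tab$pgs_sib_noncog <- NA_real_
  rf <- tab$rearing_family_id[off]
  for (cc in c("cog", "noncog")) {
    x <- tab[[paste0("pgs_", cc)]][off]
    tot <- unname(tapply(x, rf, sum)[as.character(rf)])
    n <- unname(tapply(x, rf, length)[as.character(rf)])
    tab[[paste0("pgs_sib_", cc)]][off] <- ifelse(n > 1, (tot - x) / (n - 1),
                                                 NA_real_)
    tab$n_sibs[off] <- as.integer(n)
  }
  rownames(tab) <- NULL
  attr(tab, "scale") <- "raw"
  tab
}

#' Trio composites of transmitted and non-transmitted scores
#'
#' The transmitted composite is the sum of the paternal and maternal
#' transmitted scores (identically the offspring's own raw score); the
#' non-transmitted composite averages (default) or sums the two parental
#' non-transmitted scores. Each composite is then standardized to mean 0,
#' SD 1 over the trio sample separately. The two conventions differ only by
#' a factor that the standardization absorbs.
#'
#' @param tab a raw-scale score table from [score_table()].
#' @param convention `"average"` (default) or `"sum"` for the
#'   non-transmitted composite.
#' @return the offspring rows with both parents available, with added
#'   standardized columns `pgs_t_cog`, `pgs_t_noncog`, `pgs_nt_cog`,
#'   `pgs_nt_noncog`; scale tag `"trio-convention"`. The number of rows
#'   dropped for missing parental scores is reported in attribute
#'   `"n_dropped"`.
#' @export
build_trio_scores <- function(tab, convention = c("average", "sum")) {
  convention <- match.arg(convention)
  off <- tab[tab$role == "offspring", ]
  need <- c("pgs_t_pat_cog", "pgs_t_mat_cog", "pgs_nt_pat_cog",
            "pgs_nt_mat_cog", "pgs_t_pat_noncog", "pgs_t_mat_noncog",
            "pgs_nt_pat_noncog", "pgs_nt_mat_noncog")
  keep <- stats::complete.cases(off[, need])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " offspring dropped for missing parental scores")
  }
  off <- off[keep, ]
  agg <- if (convention == "average") function(a, b) (a + b) / 2 else `+`
  for (cc in c("cog", "noncog")) {
    t_raw <- off[[paste0("pgs_t_pat_", cc)]] + off[[paste0("pgs_t_mat_", cc)]]
    nt_raw <- agg(off[[paste0("pgs_nt_pat_", cc)]],
                  off[[paste0("pgs_nt_mat_", cc)]])
    off[[paste0("pgs_t_", cc)]] <- zscale(t_raw, "transmitted composite")
    off[[paste0("pgs_nt_", cc)]] <- zscale(nt_raw, "non-transmitted composite")
    off[[paste0("pgs_t_raw_", cc)]] <- t_raw
    off[[paste0("pgs_nt_raw_", cc)]] <- nt_raw
  }
  attr(off, "scale") <- "trio-convention"
  attr(off, "n_dropped") <- n_dropped
  off
}

#' Apply a design's standardization rule to a score table
#'
#' * `sibling`: restrict to non-adopted offspring in families with at least
#'   two offspring, scale the PGS over that sibling sample, then form the
#'   family mean (`pgs_*_fam`) and within-family deviation (`pgs_*_dev`),
#'   which sum back to the scaled score exactly.
#' * `adoption`: restrict to offspring and scale the PGS within adoptees and
#'   non-adopted individuals separately (`pgs_*_z`, with a `group` column).
#' * `trio`: delegate to [build_trio_scores()].
#'
#' @param tab raw-scale score table from [score_table()].
#' @param design `"sibling"`, `"adoption"` or `"trio"`.
#' @param ... passed to [build_trio_scores()] for the trio design.
#' @return the restricted, scaled table; scale tag attribute set.
#' @export
standardize_for_design <- function(tab, design = c("sibling", "adoption",
                                                   "trio"), ...) {
  design <- match.arg(design)
  if (design == "trio") {
    return(build_trio_scores(tab, ...))
  }
  off <- tab[tab$role == "offspring", ]
  if (design == "sibling") {
    off <- off[!off$adopted, ]
    fam_n <- table(off$family_id)
    keep_fam <- names(fam_n)[fam_n >= 2]
    n_dropped <- sum(!off$family_id %in% as.integer(keep_fam))
    if (n_dropped > 0) {
      message(n_dropped, " singleton offspring dropped from sibling sample")
    }
    off <- off[off$family_id %in% as.integer(keep_fam), ]
    if (nrow(off) == 0) {
      stop("no families with two or more offspring", call. = FALSE)
    }
    for (cc in c("cog", "noncog")) {
      z <- zscale(off[[paste0("pgs_", cc)]], "sibling-sample PGS")
      fam_mean <- stats::ave(z, off$family_id)
      off[[paste0("pgs_", cc, "_z")]] <- z
      off[[paste0("pgs_", cc, "_fam")]] <- fam_mean
      off[[paste0("pgs_", cc, "_dev")]] <- z - fam_mean
    }
    attr(off, "scale") <- "sibling-sample"
  } else {
    off$group <- ifelse(off$adopted, "adopted", "nonadopted")
    if (!any(off$adopted)) {
      stop("adoption design needs a non-empty adoptee group", call. = FALSE)
    }
    for (cc in c("cog", "noncog")) {
      x <- off[[paste0("pgs_", cc)]]
      z <- x
      for (g in c("adopted", "nonadopted")) {
        sel <- off$group == g
        z[sel] <- zscale(x[sel], paste0(g, "-group PGS"))
      }
      off[[paste0("pgs_", cc, "_z")]] <- z
    }
    attr(off, "scale") <- "adoptee/nonadopted-group"
  }
  rownames(off) <- NULL
  off
}

#' Ancestry principal components
#'
#' Column-standardizes the dosage matrix over a fitting set (zero-variance
#' SNPs dropped with a message), computes the top-K left singular vectors on
#' the fitting set, and projects all rows onto the corresponding axes. The
#' PCs are orthogonal over the fitting set.
#'
#' @param dos dosage matrix (persons x SNPs).
#' @param K number of components (default 10).
#' @param fit_rows row indices of the fitting set (default: all rows).
#' @return list with `pcs` (all persons x K, projected), `sdev`
#'   (singular values / sqrt(n_fit - 1)), `fit_rows`, `kept_snps`.
#' @export
compute_pcs <- function(dos, K = 10, fit_rows = NULL) {
  stopifnot(is.matrix(dos))
  fit_rows <- fit_rows %||% seq_len(nrow(dos))
  K <- check_count(K, "K")
  if (length(fit_rows) < K + 1) {
    stop("need at least K + 1 fitting individuals", call. = FALSE)
  }
  X <- dos[fit_rows, , drop = FALSE]
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) {
    message(sum(!keep), " zero-variance SNPs dropped before PCA")
  }
  if (sum(keep) < K) stop("K exceeds the rank of the dosage matrix",
                          call. = FALSE)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")

  n <- nrow(Xs)
  if (n <= ncol(Xs)) {
    # Gram-matrix route: eigen of the n x n crossproduct
    G <- tcrossprod(Xs)
    eg <- eigen(G, symmetric = TRUE)
    d2 <- pmax(eg$values, 0)
    pos <- d2 > max(d2) * 1e-9
    if (sum(pos) < K) stop("K exceeds the rank of the dosage matrix",
                           call. = FALSE)
    U <- eg$vectors[, seq_len(K), drop = FALSE]
    d <- sqrt(d2[seq_len(K)])
  } else {
    sv <- svd(Xs, nu = K, nv = 0)
    if (sum(sv$d > max(sv$d) * 1e-9) < K) {
      stop("K exceeds the rank of the dosage matrix", call. = FALSE)
    }
    U <- sv$u
    d <- sv$d[seq_len(K)]
  }
  # loadings V = X' U / d; projection of any person x = x_std %*% V
  V <- crossprod(Xs, U) / rep(d, each = ncol(Xs))
  All <- sweep(sweep(dos[, keep, drop = FALSE], 2, mu[keep]), 2,
               sdv[keep], "/")
  pcs <- All %*% V
  colnames(pcs) <- paste0("pc", seq_len(K))
  rownames(pcs) <- rownames(dos)
  list(pcs = pcs, sdev = d / sqrt(length(fit_rows) - 1),
       fit_rows = fit_rows, kept_snps = which(keep))
}

#' Ancestry PCs for a cohort
#'
#' Fits the PCA on one founder per family (the fathers: a maximal unrelated
#' set) and projects every person, mimicking cohort pipelines that fit PCs
#' on unrelated individuals.
#'
#' @param cohort a `family_cohort`.
#' @param K number of components.
#' @return matrix persons x K aligned with `cohort$persons`.
#' @export
cohort_pcs <- function(cohort, K = 10) {
  stopifnot(inherits(cohort, "family_cohort"))
  dos <- dosages(cohort)
  fit <- which(cohort$persons$role == "father")
  compute_pcs(dos, K = K, fit_rows = fit)$pcs
}
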