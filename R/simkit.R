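# Synthetic family-cohort generator: allele frequencies, founders, spousal
# pairing, meiosis with recorded transmission, adoption, weight noise and the
# phenotype model. All loci are unlinked and biallelic; the designs depend on
# transmission only, not linkage.

#' Draw per-subpopulation allele frequencies
#'
#' Ancestral frequencies are uniform on `[maf_low, maf_high]`; each
#' subpopulation draws its frequency from the Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with divergence `fst`, truncated away from
#' 0 and 1. `fst = 0` returns the ancestral frequencies for every
#' subpopulation.
#'
#' @param m_snps number of SNPs.
#' @param n_subpops number of subpopulations.
#' @param fst divergence parameter (>= 0).
#' @param maf_low,maf_high ancestral frequency bounds in (0, 0.5].
#' @param seed integer seed.
#' @return data.frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `p_anc`, and one `p_pop<k>` column per subpopulation.
#' @examples
#' draw_allele_freqs(5, 2, fst = 0.1, seed = 1)
#' @export
draw_allele_freqs <- function(m_snps, n_subpops = 1, fst = 0,
                              maf_low = 0.05, maf_high = 0.5, seed = 1) {
  m_snps <- check_count(m_snps, "m_snps")
  n_subpops <- check_count(n_subpops, "n_subpops")
  if (!is.numeric(fst) || length(fst) != 1L || fst < 0) {
    stop_param("`fst` must be >= 0")
  }
  check_prob(maf_low, "maf_low", lo = 0, hi = 0.5, lo_open = TRUE)
  check_prob(maf_high, "maf_high", lo = 0, hi = 0.5, lo_open = TRUE)
  if (maf_low > maf_high) stop_param("`maf_low` must be <= `maf_high`")

  set.seed(seed)
  p_anc <- stats::runif(m_snps, maf_low, maf_high)
  eps <- 1e-6
  pops <- matrix(p_anc, nrow = m_snps, ncol = n_subpops)
  if (fst > 0) {
    lambda <- (1 - fst) / fst
    for (k in seq_len(n_subpops)) {
      pk <- stats::rbeta(m_snps, p_anc * lambda, (1 - p_anc) * lambda)
      pops[, k] <- pmin(pmax(pk, eps), 1 - eps)
    }
  }
  colnames(pops) <- paste0("p_pop", seq_len(n_subpops))
  out <- data.frame(
    snp = sprintf("snp%05d", seq_len(m_snps)),
    effect_allele = "A", other_allele = "G",
    p_anc = p_anc, stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(pops))
}

#' Draw true per-SNP weights for the Cog and NonCog constructs
#'
#' Independent Gaussian weights with SD `1/sqrt(m_snps)` per construct, so
#' true scores have O(1) variance regardless of the SNP count.
#'
#' @param m_snps number of SNPs (or a frequency table from
#'   [draw_allele_freqs()], whose SNP ids are reused).
#' @param sd weight SD; default `1/sqrt(m_snps)`.
#' @param seed integer seed.
#' @return a weight table: `snp`, `effect_allele`, `weight_cog`,
#'   `weight_noncog`, `provenance` (= "true").
#' @export
draw_true_weights <- function(m_snps, sd = NULL, seed = 1) {
  if (is.data.frame(m_snps)) {
    snp <- m_snps$snp
    ea <- m_snps$effect_allele
    m <- length(snp)
  } else {
    m <- check_count(m_snps, "m_snps")
    snp <- sprintf("snp%05d", seq_len(m))
    ea <- rep("A", m)
  }
  sd <- sd %||% (1 / sqrt(m))
  set.seed(seed)
  data.frame(
    snp = snp, effect_allele = ea,
    weight_cog = stats::rnorm(m, 0, sd),
    weight_noncog = stats::rnorm(m, 0, sd),
    provenance = "true", stringsAsFactors = FALSE
  )
}

#' Mix true weights with noise to a target score precision
#'
#' Returns weights `w + b * eta` with `eta ~ N(0, 1)` i.i.d. per SNP and `b`
#' chosen so that, in expectation over genotypes at the given allele
#' frequencies, the squared correlation between the noisy-weight score and
#' the true score equals `pgs_precision`. Precision 1 returns the input
#' weights unchanged.
#'
#' @param true_weights a weight table as from [draw_true_weights()].
#' @param pgs_precision target squared correlation in (0, 1].
#' @param freqs frequency table from [draw_allele_freqs()] (per-SNP variance
#'   `2p(1-p)` is taken at the subpopulation-average frequency).
#' @param seed integer seed.
#' @return a weight table with `provenance = "noisy"`.
#' @export
make_noisy_weights <- function(true_weights, pgs_precision, freqs, seed = 1) {
  check_prob(pgs_precision, "pgs_precision", lo = 0, hi = 1, lo_open = TRUE)
  stopifnot(is.data.frame(true_weights),
            all(c("weight_cog", "weight_noncog") %in% names(true_weights)))
  if (pgs_precision == 1) {
    return(true_weights)
  }
  pcols <- grep("^p_pop", names(freqs), value = TRUE)
  p <- if (length(pcols)) {
    rowMeans(as.data.frame(freqs[, pcols, drop = FALSE]))
  } else {
    freqs$p_anc
  }
  v <- 2 * p * (1 - p)  # per-SNP dosage variance
  out <- true_weights
  set.seed(seed)
  for (col in c("weight_cog", "weight_noncog")) {
    w <- true_weights[[col]]
    s_true <- sum(v * w^2)
    if (s_true == 0) {
      stop_param(sprintf("degenerate target: all-zero true weights in `%s`",
                         col))
    }
    # r^2 between score(w + b*eta) and score(w) = S_t / (S_t + b^2 * sum(v)),
    # in expectation over independent eta.
    b <- sqrt(s_true * (1 - pgs_precision) / pgs_precision / sum(v))
    out[[col]] <- w + b * stats::rnorm(length(w))
  }
  out$provenance <- "noisy"
  out
}

#' Simulate founder individuals
#'
#' Generates `2 * n_families` founders (equal numbers of prospective fathers
#' and mothers), with two haplotypes per person drawn Bernoulli at the
#' subpopulation frequency independently per locus. Subpopulations are
#' assigned in balanced blocks within each sex so that every subpopulation
#' holds equally many prospective fathers and mothers. True scores are
#' dosage-weight sums, standardized within the founder pool.
#'
#' @param scenario a [sim_scenario()].
#' @param freqs optional frequency table (drawn from the scenario otherwise).
#' @param weights optional true weight table (drawn otherwise).
#' @return a `founder_pool`: list with `persons` (person_id, sex, subpop),
#'   `hap1`, `hap2` (integer matrices persons x SNPs), `z` (true standardized
#'   scores, columns `cog`, `noncog`), `score_center`, `score_scale`,
#'   `freqs`, `weights`.
#' @export
simulate_founders <- function(scenario, freqs = NULL, weights = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n <- scenario$n_families
  m <- scenario$m_snps
  freqs <- freqs %||% draw_allele_freqs(
    m, scenario$n_subpops, scenario$fst,
    scenario$maf_low, scenario$maf_high,
    seed = derive_seed(scenario$seed, 1L)
  )
  weights <- weights %||% draw_true_weights(
    freqs, seed = derive_seed(scenario$seed, 2L)
  )
  set.seed(derive_seed(scenario$seed, 3L))

  n_tot <- 2L * n
  sex <- rep(c("M", "F"), each = n)
  subpop <- rep(rep_len(seq_len(scenario$n_subpops), n), times = 2L)
  pmat <- as.matrix(freqs[, grep("^p_pop", names(freqs)), drop = FALSE])
  p_person <- pmat[, subpop, drop = FALSE]  # m x n_tot

  hap1 <- matrix(stats::rbinom(n_tot * m, 1L, as.vector(p_person)),
                 nrow = n_tot, ncol = m, byrow = TRUE)
  hap2 <- matrix(stats::rbinom(n_tot * m, 1L, as.vector(p_person)),
                 nrow = n_tot, ncol = m, byrow = TRUE)
  colnames(hap1) <- colnames(hap2) <- freqs$snp

  dos <- hap1 + hap2
  raw <- dos %*% cbind(cog = weights$weight_cog,
                       noncog = weights$weight_noncog)
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, stats::sd)
  if (any(!is.finite(scl)) || any(scl == 0)) {
    stop_param("degenerate true scores: zero variance in the founder pool ",
               "(all-zero weights?)")
  }
  z <- sweep(sweep(raw, 2, ctr), 2, scl, "/")

  structure(list(
    persons = data.frame(person_id = seq_len(n_tot), sex = sex,
                         subpop = subpop, stringsAsFactors = FALSE),
    hap1 = hap1, hap2 = hap2, z = z,
    score_center = ctr, score_scale = scl,
    freqs = freqs, weights = weights
  ), class = "founder_pool")
}

#' Pair founders into couples with a target spousal correlation
#'
#' Matching is done within subpopulation. For `am_rho = 0` pairing is random.
#' Otherwise a Gaussian coupling is used: the males' mating-trait normal
#' ranks `x` are blurred to `w = am_rho * x + sqrt(1 - am_rho^2) * e`, and the
#' female with trait rank `r(w)` is paired to each male, which yields a
#' realized spousal Pearson correlation of about `am_rho` for near-Gaussian
#' traits. One round of assortment (disequilibrium regime).
#'
#' @param founders a `founder_pool`.
#' @param am_rho target spousal correlation in [0, 1).
#' @param mating_trait `"pgs"` (standardized sum of the two construct scores)
#'   or `"phenotype"` (direct-effect parental phenotype plus residual noise).
#' @param seed integer seed.
#' @param beta_direct named vector `c(cog=, noncog=)` used for the
#'   `"phenotype"` trait.
#' @param resid_sd residual SD for the `"phenotype"` trait.
#' @return data.frame `family_id`, `father_id`, `mother_id`, `subpop`,
#'   with the realized trait values as attributes `trait_father`,
#'   `trait_mother`.
#' @export
pair_spouses <- function(founders, am_rho = 0,
                         mating_trait = c("pgs", "phenotype"), seed = 1,
                         beta_direct = c(cog = 0.15, noncog = 0.15),
                         resid_sd = 1) {
  stopifnot(inherits(founders, "founder_pool"))
  mating_trait <- match.arg(mating_trait)
  check_prob(am_rho, "am_rho", lo = 0, hi = 1, hi_open = TRUE)
  set.seed(seed)

  per <- founders$persons
  trait <- switch(mating_trait,
    pgs = (founders$z[, "cog"] + founders$z[, "noncog"]) / sqrt(2),
    phenotype = beta_direct[["cog"]] * founders$z[, "cog"] +
      beta_direct[["noncog"]] * founders$z[, "noncog"] +
      stats::rnorm(nrow(per), 0, resid_sd)
  )

  fam <- 0L
  rows <- vector("list", length(unique(per$subpop)))
  for (k in sort(unique(per$subpop))) {
    males <- which(per$sex == "M" & per$subpop == k)
    females <- which(per$sex == "F" & per$subpop == k)
    if (length(males) != length(females)) {
      stop("unbalanced sexes within subpopulation ", k, call. = FALSE)
    }
    nk <- length(males)
    if (am_rho == 0) {
      mate <- sample(females, nk)
    } else {
      x <- zscale(trait[males], "mating trait")
      w <- am_rho * x + sqrt(1 - am_rho^2) * stats::rnorm(nk)
      # female with the r-th smallest trait goes to the male with the r-th
      # smallest blurred trait
      mate <- integer(nk)
      mate[order(w)] <- females[order(trait[females])]
    }
    rows[[k]] <- data.frame(
      family_id = fam + seq_len(nk),
      father_id = per$person_id[males],
      mother_id = per$person_id[mate],
      subpop = k
    )
    fam <- fam + nk
  }
  couples <- do.call(rbind, rows)
  rownames(couples) <- NULL
  attr(couples, "trait_father") <- trait[couples$father_id]
  attr(couples, "trait_mother") <- trait[couples$mother_id]
  couples
}

# Build the per-family offspring plan (counts and zygosity labels).
offspring_plan <- function(scenario, n_families, seed) {
  set.seed(seed)
  n_off <- if (length(scenario$offspring_per_family) == 1L) {
    rep(scenario$offspring_per_family, n_families)
  } else {
    sample(scenario$offspring_per_family, n_families, replace = TRUE)
  }
  u <- stats::runif(n_families)
  zyg <- ifelse(u < scenario$mz_fraction, "MZ",
                ifelse(u < scenario$mz_fraction + scenario$dz_fraction,
                       "DZ", "none"))
  zyg[n_off < 2L] <- "none"  # twins need two offspring
  data.frame(family_id = seq_len(n_families), n_offspring = n_off,
             zygosity = zyg, stringsAsFactors = FALSE)
}

#' Generate offspring by Mendelian meiosis
#'
#' For each offspring and each parent, one of the two parental alleles is
#' chosen independently per locus with probability 1/2, and the choice is
#' recorded as a transmission flag (1 or 2 = parental haplotype index). MZ
#' co-twins duplicate one meiosis (and share sex and age); DZ co-twins are
#' independent meioses that share age.
#'
#' @param founders a `founder_pool`.
#' @param couples output of [pair_spouses()].
#' @param plan offspring plan (data.frame `family_id`, `n_offspring`,
#'   `zygosity`) as from the scenario; built internally by
#'   [simulate_cohort()].
#' @param scenario the [sim_scenario()] (for age ranges).
#' @param seed integer seed.
#' @return a `family_cohort` object; see [simulate_cohort()].
#' @export
meiose <- function(founders, couples, plan, scenario, seed = 1) {
  stopifnot(inherits(founders, "founder_pool"))
  set.seed(seed)
  m <- ncol(founders$hap1)
  n_par <- nrow(founders$persons)

  fam_of_parent <- integer(n_par)
  fam_of_parent[couples$father_id] <- couples$family_id
  fam_of_parent[couples$mother_id] <- couples$family_id

  # expand offspring rows
  fam_idx <- rep(plan$family_id, plan$n_offspring)
  birth_order <- sequence(plan$n_offspring)
  n_off <- length(fam_idx)
  fid <- couples$father_id[fam_idx]
  mid <- couples$mother_id[fam_idx]

  trans_pat <- matrix(sample.int(2L, n_off * m, replace = TRUE),
                      nrow = n_off, ncol = m)
  trans_mat <- matrix(sample.int(2L, n_off * m, replace = TRUE),
                      nrow = n_off, ncol = m)

  pick <- function(h1, h2, tr) h1 * (tr == 1L) + h2 * (tr == 2L)
  off_hap1 <- pick(founders$hap1[fid, , drop = FALSE],
                   founders$hap2[fid, , drop = FALSE], trans_pat)
  off_hap2 <- pick(founders$hap1[mid, , drop = FALSE],
                   founders$hap2[mid, , drop = FALSE], trans_mat)

  zyg_fam <- plan$zygosity[fam_idx]
  zyg <- ifelse(zyg_fam != "none" & birth_order <= 2L, zyg_fam, "none")

  # alternate sexes within a family, offset by family parity so that
  # first-borns (the adoptee pool) are an even sex mix
  sex_off <- ifelse((birth_order + fam_idx) %% 2L == 1L, "M", "F")
  age_fam <- stats::runif(nrow(plan), scenario$age_range_offspring[1],
                          scenario$age_range_offspring[2])
  age_off <- stats::runif(n_off, scenario$age_range_offspring[1],
                          scenario$age_range_offspring[2])
  # twins (first two offspring of MZ/DZ families) share the family twin age
  is_twin <- zyg != "none"
  age_off[is_twin] <- age_fam[fam_idx][is_twin]

  # MZ: second twin duplicates the first twin's meiosis and sex
  mz_first <- which(zyg == "MZ" & birth_order == 1L)
  if (length(mz_first)) {
    mz_second <- mz_first + 1L  # offspring of a family are contiguous
    stopifnot(all(fam_idx[mz_second] == fam_idx[mz_first]),
              all(zyg[mz_second] == "MZ"))
    off_hap1[mz_second, ] <- off_hap1[mz_first, ]
    off_hap2[mz_second, ] <- off_hap2[mz_first, ]
    trans_pat[mz_second, ] <- trans_pat[mz_first, ]
    trans_mat[mz_second, ] <- trans_mat[mz_first, ]
    sex_off[mz_second] <- sex_off[mz_first]
  }

  off_id <- n_par + seq_len(n_off)
  age_par <- stats::runif(n_par, scenario$age_range_parent[1],
                          scenario$age_range_parent[2])

  persons <- data.frame(
    person_id = c(founders$persons$person_id, off_id),
    family_id = c(fam_of_parent, fam_idx),
    rearing_family_id = c(fam_of_parent, fam_idx),
    father_id = c(rep(NA_integer_, n_par), fid),
    mother_id = c(rep(NA_integer_, n_par), mid),
    role = c(ifelse(founders$persons$sex == "M", "father", "mother"),
             rep("offspring", n_off)),
    zygosity = c(rep("none", n_par), zyg),
    adopted = FALSE,
    subpop = c(founders$persons$subpop, couples$subpop[fam_idx]),
    sex = c(founders$persons$sex, sex_off),
    age = c(age_par, age_off),
    stringsAsFactors = FALSE
  )

  hap1 <- rbind(founders$hap1, off_hap1)
  hap2 <- rbind(founders$hap2, off_hap2)
  rownames(hap1) <- rownames(hap2) <- persons$person_id

  # true scores for everyone on the founder-pool scale
  dos_off <- off_hap1 + off_hap2
  raw_off <- dos_off %*% cbind(cog = founders$weights$weight_cog,
                               noncog = founders$weights$weight_noncog)
  z_off <- sweep(sweep(raw_off, 2, founders$score_center), 2,
                 founders$score_scale, "/")
  z <- rbind(founders$z, z_off)
  rownames(z) <- persons$person_id
  rownames(trans_pat) <- rownames(trans_mat) <- off_id

  structure(list(
    persons = persons, hap1 = hap1, hap2 = hap2,
    trans_pat = trans_pat, trans_mat = trans_mat,
    z = z, freqs = founders$freqs, weights_true = founders$weights,
    score_center = founders$score_center,
    score_scale = founders$score_scale,
    scenario = scenario
  ), class = "family_cohort")
}

#' Reassign a fraction of offspring to adoptive families
#'
#' Within each subpopulation, `adoption_fraction` of the families donate
#' their first offspring to a rearing family drawn from a disjoint set of
#' families in the same subpopulation (one adoptee per rearing family, whose
#' own offspring are retained). Placement is random within subpopulation, so
#' adoptees are genetically unrelated to their adoptive parents; biological
#' links are retained for prenatal effects.
#'
#' @param cohort a `family_cohort`.
#' @param adoption_fraction fraction in [0, 1); values above 0.5 per
#'   subpopulation cannot be placed uniquely and raise an error.
#' @param seed integer seed.
#' @return the cohort with updated `rearing_family_id` and `adopted` flags.
#' @export
assign_adoption <- function(cohort, adoption_fraction, seed = 1) {
  stopifnot(inherits(cohort, "family_cohort"))
  check_prob(adoption_fraction, "adoption_fraction", hi = 1, hi_open = TRUE)
  if (adoption_fraction == 0) {
    return(cohort)
  }
  set.seed(seed)
  per <- cohort$persons
  off <- per[per$role == "offspring", ]
  fam_subpop <- off$subpop[!duplicated(off$family_id)]
  names(fam_subpop) <- off$family_id[!duplicated(off$family_id)]

  for (k in sort(unique(fam_subpop))) {
    fams <- as.integer(names(fam_subpop)[fam_subpop == k])
    n_adopt <- round(adoption_fraction * length(fams))
    if (n_adopt == 0) next
    if (2L * n_adopt > length(fams)) {
      stop("adoption fraction too large to place adoptees uniquely ",
           "(needs disjoint donor and rearing families)", call. = FALSE)
    }
    chosen <- sample(fams, 2L * n_adopt)
    donors <- chosen[seq_len(n_adopt)]
    rearers <- chosen[n_adopt + seq_len(n_adopt)]
    # adoptee = first offspring of each donor family
    for (i in seq_len(n_adopt)) {
      idx <- which(per$role == "offspring" & per$family_id == donors[i])[1]
      per$rearing_family_id[idx] <- rearers[i]
      per$adopted[idx] <- TRUE
    }
  }
  cohort$persons <- per
  cohort
}

#' Simulate offspring phenotypes
#'
#' Offspring phenotype = sum over constructs of direct, biological prenatal
#' mid-parent, rearing postnatal mid-parent and rearing co-sibling effects on
#' true standardized scores, plus a subpopulation environmental shift (tied
#' to the rearing family's subpopulation) and Gaussian residual noise.
#' Singletons receive no sibling term. Parents get `NA` phenotypes.
#'
#' @param cohort a `family_cohort`.
#' @param scenario the [sim_scenario()] holding the effect sizes.
#' @param seed integer seed.
#' @return the cohort with a `y` column added to `persons`.
#' @export
simulate_outcome <- function(cohort, scenario, seed = 1) {
  stopifnot(inherits(cohort, "family_cohort"))
  per <- cohort$persons
  off <- which(per$role == "offspring")
  if (any(is.na(per$father_id[off])) || any(is.na(per$mother_id[off]))) {
    stop("missing biological parents for some offspring", call. = FALSE)
  }
  set.seed(seed)
  z <- cohort$z

  # rearing parents: the couple of the rearing family
  fam_father <- tapply(per$person_id[per$role == "father"],
                       per$family_id[per$role == "father"], identity)
  fam_mother <- tapply(per$person_id[per$role == "mother"],
                       per$family_id[per$role == "mother"], identity)
  rf <- as.character(per$rearing_family_id[off])
  rear_fid <- unname(fam_father[rf])
  rear_mid <- unname(fam_mother[rf])
  if (any(is.na(rear_fid)) || any(is.na(rear_mid))) {
    stop("missing rearing parents for some offspring", call. = FALSE)
  }

  mid_bio <- (z[per$father_id[off], , drop = FALSE] +
                z[per$mother_id[off], , drop = FALSE]) / 2
  mid_rear <- (z[rear_fid, , drop = FALSE] + z[rear_mid, , drop = FALSE]) / 2

  # rearing co-sibling score term: sum (default) or mean over co-siblings,
  # 0 for singletons
  sib_mean <- matrix(0, length(off), 2,
                     dimnames = list(NULL, c("cog", "noncog")))
  rf_int <- per$rearing_family_id[off]
  agg <- scenario$sibling_aggregate %||% "sum"
  for (col in c("cog", "noncog")) {
    zo <- z[per$person_id[off], col]
    fam_sum <- tapply(zo, rf_int, sum)
    fam_n <- tapply(zo, rf_int, length)
    key <- as.character(rf_int)
    tot <- unname(fam_sum[key])
    n_in_fam <- unname(fam_n[key])
    co_sum <- tot - zo
    sib_mean[, col] <- ifelse(
      n_in_fam > 1,
      if (agg == "sum") co_sum else co_sum / (n_in_fam - 1),
      0
    )
  }

  zo <- z[per$person_id[off], , drop = FALSE]
  rear_subpop <- per$subpop[match(rear_fid, per$person_id)]
  y <- scenario$beta_direct_cog * zo[, "cog"] +
    scenario$beta_direct_noncog * zo[, "noncog"] +
    scenario$beta_prenatal_cog * mid_bio[, "cog"] +
    scenario$beta_prenatal_noncog * mid_bio[, "noncog"] +
    scenario$beta_postnatal_cog * mid_rear[, "cog"] +
    scenario$beta_postnatal_noncog * mid_rear[, "noncog"] +
    scenario$beta_sibling_cog * sib_mean[, "cog"] +
    scenario$beta_sibling_noncog * sib_mean[, "noncog"] +
    scenario$strat_env_shift * (rear_subpop - 1) +
    stats::rnorm(length(off), 0, scenario$resid_sd)

  per$y <- NA_real_
  per$y[off] <- y
  cohort$persons <- per
  cohort
}

#' Simulate a complete family cohort from a scenario
#'
#' Runs the full generative pipeline: allele frequencies, true weights,
#' founders, spousal pairing, meiosis, adoption, noisy measurement weights
#' and phenotypes. Every stage draws from an independent stream derived from
#' `scenario$seed`, so results are bit-reproducible.
#'
#' @param scenario a [sim_scenario()].
#' @return a `family_cohort`: list with `persons` (person table incl. `y`),
#'   `hap1`/`hap2` (phased haplotypes; for offspring, hap1 = paternal
#'   transmitted, hap2 = maternal transmitted), `trans_pat`/`trans_mat`
#'   (which parental haplotype was transmitted, offspring x SNP),
#'   `z` (true standardized scores), `freqs`, `weights_true`,
#'   `weights_meas`, `scenario`.
#' @examples
#' co <- simulate_cohort(sim_scenario(n_families = 100, m_snps = 50, seed = 1))
#' head(co$persons)
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  founders <- simulate_founders(scenario)
  couples <- pair_spouses(
    founders, scenario$am_rho, scenario$mating_trait,
    seed = derive_seed(scenario$seed, 4L),
    beta_direct = c(cog = scenario$beta_direct_cog,
                    noncog = scenario$beta_direct_noncog),
    resid_sd = scenario$resid_sd
  )
  plan <- offspring_plan(scenario, nrow(couples),
                         seed = derive_seed(scenario$seed, 5L))
  cohort <- meiose(founders, couples, plan, scenario,
                   seed = derive_seed(scenario$seed, 6L))
  cohort <- assign_adoption(cohort, scenario$adoption_fraction,
                            seed = derive_seed(scenario$seed, 7L))
  cohort$weights_meas <- make_noisy_weights(
    cohort$weights_true, scenario$pgs_precision, cohort$freqs,
    seed = derive_seed(scenario$seed, 8L)
  )
  simulate_outcome(cohort, scenario, seed = derive_seed(scenario$seed, 9L))
}

#' @export
print.family_cohort <- function(x, ...) {
  per <- x$persons
  cat("<family_cohort>\n")
  cat(sprintf("  %d persons (%d offspring) in %d families, %d SNPs\n",
              nrow(per), sum(per$role == "offspring"),
              length(unique(per$family_id)), ncol(x$hap1)))
  cat(sprintf("  adopted: %d  MZ: %d  DZ: %d  subpops: %d\n",
              sum(per$adopted), sum(per$zygosity == "MZ"),
              sum(per$zygosity == "DZ"), length(unique(per$subpop))))
  invisible(x)
}

#' Allele dosages of a cohort
#'
#' @param cohort a `family_cohort`.
#' @param persons optional person ids (default all).
#' @return integer matrix persons x SNPs, `hap1 + hap2`.
#' @export
dosages <- function(cohort, persons = NULL) {
  stopifnot(inherits(cohort, "family_cohort"))
  d <- cohort$hap1 + cohort$hap2
  if (!is.null(persons)) d <- d[as.character(persons), , drop = FALSE]
  d
}
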