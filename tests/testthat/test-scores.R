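# Polygenic score computation, transmitted/non-transmitted identities,
# design standardization rules and ancestry PCs.

test_that("compute_pgs is the weighted allele sum", {
  dos <- rbind(a = c(s1 = 0, s2 = 1, s3 = 2), b = c(2, 0, 1))
  colnames(dos) <- c("s1", "s2", "s3")
  w <- data.frame(snp = c("s1", "s2", "s3"), effect_allele = "A",
                  weight_cog = c(0.5, -1, 0.25), weight_noncog = 0)
  s <- compute_pgs(dos, w)
  expect_equal(unname(s[, "cog"]), c(-0.5, 1.25))
  expect_equal(unname(s[, "noncog"]), c(0, 0))

  # all-zero weights give all-zero scores
  w0 <- w
  w0$weight_cog <- 0
  expect_true(all(compute_pgs(dos, w0) == 0))

  # effect-allele flips count the complementary allele
  cnt <- c(s1 = "G", s2 = "A", s3 = "A")
  sf <- compute_pgs(dos, w, counted = cnt)
  expect_equal(unname(sf[, "cog"]), c((2 - 0) * 0.5 - 1 + 0.5,
                                      (2 - 2) * 0.5 + 0 + 0.25))

  expect_error(compute_pgs(dos, data.frame(snp = "zz", effect_allele = "A",
                                           weight_cog = 1,
                                           weight_noncog = 1)),
               "SNP mismatch")
  dna <- dos
  dna[1, 2] <- NA
  expect_error(compute_pgs(dna, w), "missing")
  expect_silent(compute_pgs(dna, w, missing = "mean"))
})

test_that("compute_pgs matches a per-person loop-and-sum oracle", {
  set.seed(42)
  dos <- matrix(sample(0:2, 50 * 20, replace = TRUE), 50, 20,
                dimnames = list(NULL, paste0("s", 1:20)))
  w <- data.frame(snp = paste0("s", 1:20), effect_allele = "A",
                  weight_cog = rnorm(20), weight_noncog = rnorm(20))
  s <- compute_pgs(dos, w)
  oracle <- t(vapply(seq_len(50), function(i) {
    cc <- 0; nn <- 0
    for (j in seq_len(20)) {
      cc <- cc + dos[i, j] * w$weight_cog[j]
      nn <- nn + dos[i, j] * w$weight_noncog[j]
    }
    c(cc, nn)
  }, numeric(2)))
  expect_equal(unname(s), unname(oracle))
})

test_that("transmitted/non-transmitted scores satisfy the raw identities", {
  co <- direct_cohort()
  tab <- quiet_score_table(co)
  off <- tab[tab$role == "offspring", ]
  parents <- tab[tab$role != "offspring", ]
  for (cc in c("cog", "noncog")) {
    own <- off[[paste0("pgs_", cc)]]
    # transmitted paternal + maternal = own score, exactly
    expect_equal(off[[paste0("pgs_t_pat_", cc)]] +
                   off[[paste0("pgs_t_mat_", cc)]], own, tolerance = 1e-12)
    # transmitted + non-transmitted = the parent's own score, exactly
    f_own <- parents[[paste0("pgs_", cc)]][match(off$father_id,
                                                 parents$person_id)]
    m_own <- parents[[paste0("pgs_", cc)]][match(off$mother_id,
                                                 parents$person_id)]
    expect_equal(off[[paste0("pgs_t_pat_", cc)]] +
                   off[[paste0("pgs_nt_pat_", cc)]], f_own,
                 tolerance = 1e-12)
    expect_equal(off[[paste0("pgs_t_mat_", cc)]] +
                   off[[paste0("pgs_nt_mat_", cc)]], m_own,
                 tolerance = 1e-12)
  }
})

test_that("single-locus transmission example works by hand", {
  # father (0,1) transmitting the 1-allele with weight 2:
  # transmitted score 2, non-transmitted 0, sum = father dosage * weight
  co <- cached("twins3000", simulate_cohort(
    sim_scenario(n_families = 3000, m_snps = 100, mz_fraction = 0.3,
                 dz_fraction = 0.7, offspring_per_family = 2, seed = 55)))
  hs <- haplotype_scores(co)
  tab <- quiet_score_table(co)
  mz <- tab[tab$zygosity == "MZ", ]
  m1 <- mz[!duplicated(mz$family_id), ]
  m2 <- mz[duplicated(mz$family_id), ]
  # MZ co-twins have identical transmitted scores
  expect_equal(m1$pgs_t_pat_cog, m2$pgs_t_pat_cog, tolerance = 1e-12)
  expect_equal(m1$pgs_t_mat_noncog, m2$pgs_t_mat_noncog, tolerance = 1e-12)
})

test_that("trio composites follow the averaging convention", {
  co <- direct_cohort()
  tab <- quiet_score_table(co)
  trio <- suppressMessages(build_trio_scores(tab))
  off <- tab[tab$role == "offspring", ]
  off <- off[match(trio$person_id, off$person_id), ]
  expect_equal(trio$pgs_nt_raw_cog,
               (off$pgs_nt_pat_cog + off$pgs_nt_mat_cog) / 2,
               tolerance = 1e-12)
  trio_sum <- suppressMessages(build_trio_scores(tab, convention = "sum"))
  expect_equal(trio_sum$pgs_nt_raw_cog,
               off$pgs_nt_pat_cog + off$pgs_nt_mat_cog, tolerance = 1e-12)
  # the two conventions differ only by scale: identical after standardization
  expect_equal(trio$pgs_nt_cog, trio_sum$pgs_nt_cog, tolerance = 1e-12)
  # composites standardized to mean 0, SD 1
  expect_equal(mean(trio$pgs_t_cog), 0, tolerance = 1e-12)
  expect_equal(sd(trio$pgs_nt_noncog), 1, tolerance = 1e-12)

  # transmitted and non-transmitted variances equal under random mating
  ft <- var.test(trio$pgs_t_raw_cog, 2 * trio$pgs_nt_raw_cog)
  expect_gt(ft$p.value, 0.01)

  # degenerate constant composite errors
  bad <- tab
  bad$pgs_nt_pat_cog <- 1
  bad$pgs_nt_mat_cog <- 1
  expect_error(suppressMessages(build_trio_scores(bad)), "degenerate")
})

test_that("design standardization scales within the right groups", {
  co <- cached("adopt5000", simulate_cohort(
    direct_scenario(n_families = 5000, m_snps = 150,
                    adoption_fraction = 0.2, seed = 77)))
  tab <- quiet_score_table(co)

  sib <- suppressMessages(standardize_for_design(tab, "sibling"))
  expect_equal(mean(sib$pgs_cog_z), 0, tolerance = 1e-12)
  expect_equal(sd(sib$pgs_cog_z), 1, tolerance = 1e-12)
  expect_true(all(!sib$adopted))
  # family mean + deviation reconstructs the scaled score exactly
  expect_equal(sib$pgs_cog_fam + sib$pgs_cog_dev, sib$pgs_cog_z,
               tolerance = 1e-12)
  # deviations sum to zero within each sibship, and for 2-sib families are
  # +/- half the sibling difference
  dev_sum <- tapply(sib$pgs_noncog_dev, sib$family_id, sum)
  expect_lt(max(abs(dev_sum)), 1e-10)
  two <- sib[sib$family_id %in%
               names(which(table(sib$family_id) == 2)), ]
  s1 <- two[!duplicated(two$family_id), ]
  s2 <- two[duplicated(two$family_id), ]
  expect_equal(s1$pgs_cog_dev, (s1$pgs_cog_z - s2$pgs_cog_z) / 2,
               tolerance = 1e-12)

  adop <- standardize_for_design(tab, "adoption")
  for (g in c("adopted", "nonadopted")) {
    expect_equal(mean(adop$pgs_cog_z[adop$group == g]), 0,
                 tolerance = 1e-12)
    expect_equal(sd(adop$pgs_noncog_z[adop$group == g]), 1,
                 tolerance = 1e-12)
  }
  expect_error(standardize_for_design(tab, "nonsense"))
})

test_that("double-entry sibling ICC matches the ANOVA intraclass estimate", {
  co <- null_cohort()
  tab <- quiet_score_table(co)
  diag <- pgs_correlation_diagnostics(tab)
  icc_de <- diag$value[diag$statistic == "sibling_icc" &
                         diag$construct == "cog"]
  # mean-squares ANOVA ICC on the same pairs (oracle)
  off <- tab[tab$role == "offspring" & !tab$adopted, ]
  fam_n <- table(off$family_id)
  off <- off[off$family_id %in% names(fam_n)[fam_n == 2], ]
  x <- off$pgs_cog
  g <- factor(off$family_id)
  ms <- anova(lm(x ~ g))
  msb <- ms$`Mean Sq`[1]
  msw <- ms$`Mean Sq`[2]
  icc_anova <- (msb - msw) / (msb + msw)
  # the double-entry correlation and ANOVA ICC agree up to the (n-1)/n
  # grand-mean correction, far inside 1e-3 at this sample size
  expect_equal(icc_de, icc_anova, tolerance = 1e-3)
  # and equals the Pearson correlation of the two per-family orderings
  # averaged over both orders, to machine precision
  s1 <- off[!duplicated(off$family_id), "pgs_cog"]
  s2 <- off[duplicated(off$family_id), "pgs_cog"]
  de <- cor(c(s1, s2), c(s2, s1))
  expect_equal(icc_de, de, tolerance = 1e-6)
})

test_that("ancestry PCs separate simulated subpopulations", {
  sc <- sim_scenario(n_families = 1000, m_snps = 500, n_subpops = 2,
                     fst = 0.1, seed = 4)
  co <- simulate_cohort(sc)
  pcs <- cohort_pcs(co, K = 5)
  expect_gt(abs(cor(pcs[, 1], co$persons$subpop)), 0.9)
  # PCs orthogonal over the fitting set (fathers)
  fit_rows <- which(co$persons$role == "father")
  g <- crossprod(pcs[fit_rows, ])
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)

  # no structure: PC1 uninformative about the label
  sc0 <- sim_scenario(n_families = 1000, m_snps = 500, n_subpops = 2,
                      fst = 0, seed = 4)
  co0 <- simulate_cohort(sc0)
  pcs0 <- cohort_pcs(co0, K = 5)
  expect_lt(abs(cor(pcs0[, 1], co0$persons$subpop)), 0.15)

  # rank guard
  toy <- matrix(rep(c(0, 1, 2), 4), nrow = 4, byrow = TRUE)[, 1:3] * 0 +
    outer(c(1, 2, 3, 4), c(1, 1, 1))
  colnames(toy) <- paste0("s", 1:3)
  expect_error(suppressMessages(compute_pcs(toy, K = 2)), "rank")
})
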