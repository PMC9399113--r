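# Generative machinery: allele frequencies, founders, mating, meiosis,
# adoption, weight noise and the phenotype model.

test_that("allele frequencies follow the Balding-Nichols model", {
  # zero divergence: all subpopulations share the ancestral frequencies
  f0 <- draw_allele_freqs(100, n_subpops = 2, fst = 0, seed = 1)
  expect_identical(f0$p_pop1, f0$p_pop2)
  expect_identical(f0$p_pop1, f0$p_anc)
  expect_true(all(f0$p_anc >= 0.05 & f0$p_anc <= 0.5))

  # one population, wide divergence: a frequency in bounds
  f1 <- draw_allele_freqs(1, n_subpops = 1, fst = 0.5, maf_low = 0.1,
                          maf_high = 0.4, seed = 2)
  expect_equal(nrow(f1), 1L)
  expect_true(f1$p_pop1 > 0 && f1$p_pop1 < 1)

  # moment check: E[(p1 - p2)^2] = 2 * fst * p(1-p), so the p(1-p)-
  # standardized squared difference averages to 2 * fst
  f <- draw_allele_freqs(5000, n_subpops = 2, fst = 0.1, seed = 3)
  stat <- mean((f$p_pop1 - f$p_pop2)^2 / (f$p_anc * (1 - f$p_anc)))
  expect_lt(abs(stat - 0.2), 0.02)

  expect_error(draw_allele_freqs(10, maf_low = 0.4, maf_high = 0.2),
               "maf_low")
  expect_error(draw_allele_freqs(10, fst = -0.1), "fst")
})

test_that("founder genotypes match their subpopulation frequencies", {
  sc <- sim_scenario(n_families = 2000, m_snps = 300, seed = 7)
  fp <- simulate_founders(sc)
  expect_equal(nrow(fp$hap1), 4000L)
  expect_true(all(fp$hap1 %in% 0:1) && all(fp$hap2 %in% 0:1))
  # per-SNP dosage mean ~ 2p within Monte-Carlo error
  dos_mean <- colMeans(fp$hap1 + fp$hap2)
  p <- fp$freqs$p_pop1
  mc <- 4 * sqrt(2 * p * (1 - p) / 4000)
  expect_true(all(abs(dos_mean - 2 * p) < mc))
  # true scores standardized within the pool
  expect_equal(colMeans(fp$z), c(cog = 0, noncog = 0), tolerance = 1e-12)
  expect_equal(apply(fp$z, 2, sd), c(cog = 1, noncog = 1), tolerance = 1e-12)
})

test_that("all-zero weights make founder scores degenerate", {
  sc <- sim_scenario(n_families = 100, m_snps = 20, seed = 1)
  w <- draw_true_weights(20, seed = 1)
  w$weight_cog <- 0
  w$weight_noncog <- 0
  expect_error(simulate_founders(sc, weights = w), "degenerate")
})

test_that("spousal pairing hits the target correlation", {
  sc <- sim_scenario(n_families = 20000, m_snps = 60, seed = 31)
  fp <- cached("founders20k", simulate_founders(sc))
  trait_of <- function(cp) {
    cbind(attr(cp, "trait_father"), attr(cp, "trait_mother"))
  }
  # random mating: spousal correlation indistinguishable from zero
  cp0 <- pair_spouses(fp, am_rho = 0, seed = 1)
  t0 <- trait_of(cp0)
  expect_lt(abs(cor(t0[, 1], t0[, 2])), 3 / sqrt(nrow(cp0)))
  # target 0.2 at 20,000 couples realized within +/- 0.02
  cp2 <- pair_spouses(fp, am_rho = 0.2, seed = 2)
  t2 <- trait_of(cp2)
  expect_lt(abs(cor(t2[, 1], t2[, 2]) - 0.2), 0.02)
  # near-deterministic assortment: near-perfect rank agreement
  cp9 <- pair_spouses(fp, am_rho = 0.95, seed = 3)
  t9 <- trait_of(cp9)
  expect_gt(cor(t9[, 1], t9[, 2], method = "spearman"), 0.9)
})

test_that("meiosis respects Mendelian transmission exactly", {
  co <- null_cohort()
  per <- co$persons
  off <- per[per$role == "offspring", ]
  t_pat <- co$hap1[as.character(off$person_id), ]
  t_mat <- co$hap2[as.character(off$person_id), ]
  dos_f <- dosages(co, off$father_id)
  dos_m <- dosages(co, off$mother_id)
  # non-transmitted allele = parent dosage - transmitted allele, always 0/1
  expect_true(all((dos_f - t_pat) %in% 0:1))
  expect_true(all((dos_m - t_mat) %in% 0:1))
  # homozygous parent transmits its allele, always
  expect_true(all(t_pat[dos_f == 2] == 1L))
  expect_true(all(t_pat[dos_f == 0] == 0L))
  # transmission flags point at the transmitted haplotype
  f1 <- co$hap1[as.character(off$father_id), ]
  f2 <- co$hap2[as.character(off$father_id), ]
  picked <- f1 * (co$trans_pat == 1L) + f2 * (co$trans_pat == 2L)
  expect_identical(unname(picked), unname(t_pat))
})

test_that("MZ twins share a meiosis and DZ siblings correlate 0.5", {
  sc <- sim_scenario(n_families = 3000, m_snps = 100, mz_fraction = 0.3,
                     dz_fraction = 0.7, offspring_per_family = 2, seed = 55)
  co <- cached("twins3000", simulate_cohort(sc))
  per <- co$persons
  off <- per[per$role == "offspring", ]
  mz <- off[off$zygosity == "MZ", ]
  first <- mz[!duplicated(mz$family_id), ]
  second <- mz[duplicated(mz$family_id), ]
  expect_identical(unname(co$hap1[as.character(first$person_id), ]),
                   unname(co$hap1[as.character(second$person_id), ]))
  expect_identical(unname(co$hap2[as.character(first$person_id), ]),
                   unname(co$hap2[as.character(second$person_id), ]))
  expect_identical(first$sex, second$sex)

  dz <- off[off$zygosity == "DZ", ]
  d1 <- dz[!duplicated(dz$family_id), ]
  d2 <- dz[duplicated(dz$family_id), ]
  dosA <- dosages(co, d1$person_id)
  dosB <- dosages(co, d2$person_id)
  rs <- vapply(seq_len(ncol(dosA)),
               function(j) cor(dosA[, j], dosB[, j]), numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("adoptees are placed away from their biological family", {
  co0 <- simulate_cohort(null_scenario(n_families = 200, m_snps = 50,
                                       adoption_fraction = 0))
  expect_true(all(!co0$persons$adopted))
  expect_identical(co0$persons$family_id, co0$persons$rearing_family_id)

  sc <- direct_scenario(n_families = 5000, m_snps = 150,
                        adoption_fraction = 0.2, seed = 77)
  co <- cached("adopt5000", simulate_cohort(sc))
  per <- co$persons
  ad <- per[per$adopted, ]
  expect_gt(nrow(ad), 900)
  expect_true(all(ad$rearing_family_id != ad$family_id))
  # one adoptee per rearing family; rearing families kept their own offspring
  expect_false(anyDuplicated(ad$rearing_family_id) > 0)
  donors <- unique(ad$family_id)
  expect_equal(length(intersect(donors, unique(ad$rearing_family_id))), 0L)
  # genetic orthogonality to the adoptive parents
  tab <- quiet_score_table(co)
  f_ids <- tab[tab$role == "father", ]
  m_ids <- tab[tab$role == "mother", ]
  midp <- (f_ids$pgs_cog[match(ad$rearing_family_id, f_ids$family_id)] +
             m_ids$pgs_cog[match(ad$rearing_family_id, m_ids$family_id)]) / 2
  r <- cor(tab$pgs_cog[match(ad$person_id, tab$person_id)], midp)
  expect_lt(abs(r), 3 / sqrt(nrow(ad)))

  expect_error(assign_adoption(co, 0.7, seed = 1), "too large")
})

test_that("adoptive placement stays genetically random under assortment", {
  sc <- direct_scenario(n_families = 4000, m_snps = 120,
                        adoption_fraction = 0.2, am_rho = 0.4, seed = 78)
  co <- simulate_cohort(sc)
  tab <- quiet_score_table(co)
  ad <- tab[tab$adopted, ]
  f_ids <- tab[tab$role == "father", ]
  m_ids <- tab[tab$role == "mother", ]
  midp <- (f_ids$pgs_cog[match(ad$rearing_family_id, f_ids$family_id)] +
             m_ids$pgs_cog[match(ad$rearing_family_id, m_ids$family_id)]) / 2
  expect_lt(abs(cor(ad$pgs_cog, midp)), 3 / sqrt(nrow(ad)))
})

test_that("weight noise hits the target score precision", {
  freqs <- draw_allele_freqs(2000, seed = 5)
  w <- draw_true_weights(freqs, seed = 5)
  # precision 1 returns the weights untouched
  expect_identical(make_noisy_weights(w, 1, freqs), w)
  # degenerate all-zero target errors
  w0 <- w
  w0$weight_cog <- 0
  expect_error(make_noisy_weights(w0, 0.5, freqs), "degenerate")
  # realized r^2 on a founder pool within +/- 0.03 of the target
  sc <- sim_scenario(n_families = 5000, m_snps = 2000, seed = 5)
  fp <- simulate_founders(sc, freqs = freqs, weights = w)
  wn <- make_noisy_weights(w, 0.25, freqs, seed = 9)
  dos <- fp$hap1 + fp$hap2
  noisy <- dos %*% cbind(wn$weight_cog)
  true <- dos %*% cbind(w$weight_cog)
  expect_lt(abs(cor(noisy, true)^2 - 0.25), 0.03)
})

test_that("the phenotype model wires each effect to the right relatives", {
  # null model: phenotype is pure noise, uncorrelated with scores
  co0 <- null_cohort()
  off0 <- co0$persons[co0$persons$role == "offspring", ]
  expect_equal(sd(off0$y), 1, tolerance = 0.05)
  expect_lt(abs(cor(off0$y, co0$z[off0$person_id, "cog"])),
            3 / sqrt(nrow(off0)))

  # direct-only: regression of y on the child's true score recovers beta
  co <- direct_cohort()
  off <- co$persons[co$persons$role == "offspring", ]
  fit <- lm(off$y ~ co$z[off$person_id, "cog"] + co$z[off$person_id, "noncog"])
  expect_lt(abs(unname(coef(fit)[2]) - 0.15), 0.05)
  expect_lt(abs(unname(coef(fit)[3]) - 0.15), 0.05)

  # prenatal-only: adoptees depend on the biological, not adoptive, parents
  scp <- direct_scenario(n_families = 4000, m_snps = 150, seed = 79,
                         beta_direct_cog = 0, beta_direct_noncog = 0,
                         beta_prenatal_cog = 0.2, beta_prenatal_noncog = 0.2,
                         adoption_fraction = 0.2)
  cop <- simulate_cohort(scp)
  per <- cop$persons
  ad <- per[per$adopted, ]
  fam_f <- setNames(per$person_id[per$role == "father"],
                    per$family_id[per$role == "father"])
  fam_m <- setNames(per$person_id[per$role == "mother"],
                    per$family_id[per$role == "mother"])
  midp <- function(fam) {
    (cop$z[unname(fam_f[as.character(fam)]), "cog"] +
       cop$z[unname(fam_m[as.character(fam)]), "cog"]) / 2
  }
  fit_ad <- lm(ad$y ~ midp(ad$family_id) + midp(ad$rearing_family_id))
  ses <- sqrt(diag(vcov(fit_ad)))
  expect_lt(abs(unname(coef(fit_ad)[2]) - 0.2), 3 * ses[2])
  expect_lt(abs(unname(coef(fit_ad)[3])), 3 * ses[3])
})

test_that("seeded cohorts are bit-reproducible", {
  sc <- direct_scenario(n_families = 150, m_snps = 40, seed = 2024)
  a <- simulate_cohort(sc)
  b <- simulate_cohort(sc)
  expect_identical(a, b)
})

test_that("scenario validation rejects inconsistent parameters", {
  expect_error(sim_scenario(n_families = 1), "n_families")
  expect_error(sim_scenario(pgs_precision = 0), "pgs_precision")
  expect_error(sim_scenario(mz_fraction = 0.6, dz_fraction = 0.6),
               "mz_fraction")
  expect_error(sim_scenario(maf_low = 0.4, maf_high = 0.1), "maf_low")
  expect_error(sim_scenario(offspring_per_family = 4), "offspring")
  expect_error(sim_scenario(am_rho = 1), "am_rho")
})
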