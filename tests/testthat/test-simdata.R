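test_that("config invariants are enforced", {
  expect_error(sim_config(n_regions = 1), "n_regions")
  expect_error(sim_config(n_snps = 10, ld_block_size = 3), "divide")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(h2_direct = 0.5, var_region = 0.3, var_family = 0.3),
               "<= 1")
  expect_error(sim_config(ld_block_r = 1), "ld_block_r")
  expect_error(sim_config(w_passive = 0.8, w_active = 0.7), "w_passive")
})

test_that("region grid, SES standardization and rook adjacency are correct", {
  lay4 <- simulate_regions(sim_config(n_regions = 4, seed = 1))
  expect_equal(unname(rowSums(lay4$W)), rep(2, 4))  # 2x2: every cell 2 nbrs

  lay9 <- simulate_regions(sim_config(n_regions = 9, seed = 2))
  expect_equal(mean(lay9$regions$ses), 0, tolerance = 1e-12)
  expect_equal(stats::var(lay9$regions$ses), 1, tolerance = 1e-12)

  # brute-force neighbor count straight from the coordinates
  lay100 <- simulate_regions(sim_config(n_regions = 100, seed = 3))
  xy <- lay100$regions
  brute <- vapply(seq_len(100), function(i) {
    sum(vapply(seq_len(100), function(j) {
      i != j && abs(xy$x[i] - xy$x[j]) + abs(xy$y[i] - xy$y[j]) == 1
    }, logical(1)))
  }, numeric(1))
  expect_equal(unname(rowSums(lay100$W)), brute)
  expect_true(all(sort(unique(brute)) %in% c(2, 3, 4)))
  expect_true(isSymmetric(lay100$W))
  expect_true(all(diag(lay100$W) == 0))
})

test_that("founder genotypes are in HWE and passive sorting matches the oracle", {
  cfg <- sim_config(n_families = 10000, n_regions = 25, n_snps = 1,
                    maf_range = c(0.5, 0.5), w_passive = 0, seed = 31)
  lay <- simulate_regions(cfg)
  par <- simulate_parents(cfg, lay)
  frq <- tabulate(par$geno[, 1] + 1L, 3) / nrow(par$geno)
  expect_equal(frq, c(0.25, 0.5, 0.25), tolerance = 0.03)

  # no sorting when the passive channel is off
  ses0 <- lay$regions$ses[match(par$couples$region_birth, lay$regions$region)]
  expect_lt(abs(stats::cor(par$couples$midparent_g, ses0)), 0.02)

  # w_passive = 0.5, K = 25: Monte Carlo oracle of the latent -> rank ->
  # equal-size-bin -> region-SES mapping gives corr 0.489 (SD 0.006)
  cfg5 <- sim_config(n_families = 20000, n_regions = 25, n_snps = 200,
                     w_passive = 0.5, seed = 32)
  lay5 <- simulate_regions(cfg5)
  par5 <- simulate_parents(cfg5, lay5)
  ses5 <- lay5$regions$ses[match(par5$couples$region_birth,
                                 lay5$regions$region)]
  expect_equal(stats::cor(par5$couples$midparent_g, ses5), 0.489,
               tolerance = 0.03)
  expect_error(simulate_parents(sim_config(maf_range = c(0.6, 0.7)), lay),
               "maf_range")
})

test_that("Mendelian transmission follows the Punnett expectations", {
  snps <- tibble::tibble(snp = "rs1", maf = 0.5, block = 1L, ld_r = 0,
                         beta_true = 0, weight = 0)
  # aa x AA -> always heterozygous
  par <- structure(list(geno = matrix(c(rep(0L, 500), rep(2L, 500)), ncol = 1),
                        snps = snps), class = "parent_pop")
  kids <- transmit_genotypes(par, seed = 5)
  expect_true(all(kids$geno == 1L))

  # Aa x Aa -> 1/4, 1/2, 1/4
  par2 <- structure(list(geno = matrix(1L, 20000, 1), snps = snps),
                    class = "parent_pop")
  kids2 <- transmit_genotypes(par2, seed = 6)
  frq <- tabulate(kids2$geno[, 1] + 1L, 3) / nrow(kids2$geno)
  expect_equal(frq, c(0.25, 0.5, 0.25), tolerance = 0.02)

  par_odd <- structure(list(geno = matrix(1L, 3, 1), snps = snps),
                       class = "parent_pop")
  expect_error(transmit_genotypes(par_odd), "couples")
})

test_that("full-sibling polygenic scores correlate 0.5", {
  cfg <- sim_config(n_families = 20000, n_snps = 1000, h2_direct = 0.3,
                    pgs_noise = 0.1, seed = 41)
  sim <- simulate_sib_cohort(cfg)
  p1 <- sim$cohort$prs[sim$cohort$sib == 1]
  p2 <- sim$cohort$prs[sim$cohort$sib == 2]
  expect_equal(stats::cor(p1, p2), 0.5, tolerance = 0.02)
})

test_that("migration carries the active rGE channel and nothing else", {
  sim0 <- rge_off_sim()
  co0 <- sim0$cohort
  dev <- co0$g_true - stats::ave(co0$g_true, co0$fid)
  ses_c <- sim0$layout$regions$ses[match(co0$region_current,
                                         sim0$layout$regions$region)]
  d_dev <- dev[co0$sib == 1] - dev[co0$sib == 2]
  d_ses <- ses_c[co0$sib == 1] - ses_c[co0$sib == 2]
  expect_lt(abs(stats::cor(d_dev, d_ses)), 0.03)

  # active channel on: the higher-scoring sibling ends up in the higher-SES
  # region in more than half the discordant pairs
  sim1 <- rge_on_sim()
  co1 <- sim1$cohort
  ses1 <- sim1$layout$regions$ses[match(co1$region_current,
                                        sim1$layout$regions$region)]
  dprs <- co1$g_true[co1$sib == 1] - co1$g_true[co1$sib == 2]
  dses <- ses1[co1$sib == 1] - ses1[co1$sib == 2]
  disc <- dses != 0
  expect_gt(mean(sign(dprs[disc]) == sign(dses[disc])), 0.55)

  # near-deterministic limit: K = 2, very strong active channel
  cfg2 <- sim_config(n_families = 4000, n_regions = 2, n_snps = 200,
                     w_active = 0.95, seed = 43)
  sim2 <- simulate_sib_cohort(cfg2)
  co2 <- sim2$cohort
  ses2 <- sim2$layout$regions$ses[match(co2$region_current,
                                        sim2$layout$regions$region)]
  dprs2 <- co2$g_true[co2$sib == 1] - co2$g_true[co2$sib == 2]
  dses2 <- ses2[co2$sib == 1] - ses2[co2$sib == 2]
  disc2 <- dses2 != 0
  expect_gt(mean(sign(dprs2[disc2]) == sign(dses2[disc2])), 0.95)
})

test_that("phenotype variance structure matches the generative algebra", {
  # no rGE, no environment: Var(Y) ~ 1 and the squared PRS-phenotype
  # correlation equals h2 * h2 / (h2 + pgs_noise) (weight-noise attenuation)
  cfg <- sim_config(n_families = 10000, n_snps = 500, h2_direct = 0.3,
                    pgs_noise = 0.15, seed = 51)
  sim <- simulate_sib_cohort(cfg)
  co <- sim$cohort
  expect_equal(stats::var(co$pheno), 1, tolerance = 0.05)
  expect_lt(abs(stats::cor(co$prs, co$pheno)^2 - 0.3 * 0.3 / (0.3 + 0.15)),
            0.02)

  # pure region phenotype: variance of region means recovers var_region
  cfg_r <- sim_config(n_families = 10000, n_regions = 25, n_snps = 200,
                      h2_direct = 0, var_region = 0.2, pgs_noise = 0,
                      seed = 52)
  sim_r <- simulate_sib_cohort(cfg_r)
  rm_var <- stats::var(tapply(sim_r$cohort$pheno, sim_r$cohort$region_current,
                              mean))
  expect_lt(abs(rm_var - 0.2), 0.03)

  expect_error(
    simulate_phenotype(sim$cohort, sim$layout, cfg,
                       overrides = list(var_region = 0.5, var_family = 0.5)),
    "variance fractions")
})

test_that("ANOVA-style decomposition recovers the configured components", {
  cfg <- sim_config(n_families = 8000, n_regions = 25, n_snps = 300,
                    h2_direct = 0.3, var_region = 0.15, var_family = 0.2,
                    pgs_noise = 0, seed = 53)
  sim <- simulate_sib_cohort(cfg)
  co <- sim$cohort
  # region variance: variance of current-region means
  v_region <- stats::var(tapply(co$pheno, co$region_current, mean))
  expect_lt(abs(v_region / 0.15 - 1), 0.10)
  # within-family residual after removing the modeled signal: genetic +
  # family + region pieces leave 1 - h2 - var_region - var_family
  resid <- co$pheno - sqrt(0.3) * scale(co$g_true)[, 1] -
    sqrt(0.15) * sim$layout$regions$ses[match(co$region_current,
                                              sim$layout$regions$region)]
  d <- resid[co$sib == 1] - resid[co$sib == 2]
  expect_equal(stats::var(d) / 2, 1 - 0.3 - 0.15 - 0.2, tolerance = 0.035)
})

test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_families = 300, n_regions = 9, n_snps = 60,
                    w_passive = 0.3, w_active = 0.2, var_region = 0.1,
                    var_family = 0.1, seed = 61)
  s1 <- simulate_sib_cohort(cfg)
  s2 <- simulate_sib_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$snps, s2$snps)
  g1 <- simulate_gwas_cohort(cfg, n = 400)
  g2 <- simulate_gwas_cohort(cfg, n = 400)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$geno, g2$geno)
})

test_that("closed-form LD scores match their definition and the empirical ones", {
  expect_equal(true_ld_scores(sim_config(n_snps = 10, ld_block_size = 1))$l,
               rep(1, 10))
  tl <- true_ld_scores(sim_config(n_snps = 20, ld_block_size = 10,
                                  ld_block_r = 0.5))
  expect_equal(tl$l, rep(1 + 9 * 0.25, 20))

  cfg <- sim_config(n_families = 2500, n_snps = 400, ld_block_size = 10,
                    ld_block_r = c(0, 0.5), seed = 71)
  sim <- simulate_gwas_cohort(cfg, n = 5000)
  emp <- empirical_ld_scores(sim$geno, sim$snps$block, snps = sim$snps)
  tru <- true_ld_scores(cfg)
  by_block <- tapply(emp$l - tru$l[match(emp$snp, tru$snp)],
                     sim$snps$ld_r[match(emp$snp, sim$snps$snp)], mean)
  expect_lt(max(abs(by_block)), 0.05)
})
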