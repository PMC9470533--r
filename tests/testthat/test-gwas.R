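test_that("principal components separate structured populations", {
  set.seed(21)
  n <- 400
  m <- 150
  p1 <- runif(m, 0.1, 0.5)
  p2 <- pmin(0.95, p1 + 0.4)  # strongly diverged frequencies
  geno <- rbind(
    matrix(rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2, m),
    matrix(rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2, m)
  )
  pcs <- compute_pcs(geno, 4)
  grp <- rep(1:2, each = n / 2)
  expect_true(max(pcs[grp == 1, 1]) < min(pcs[grp == 2, 1]) ||
                min(pcs[grp == 1, 1]) > max(pcs[grp == 2, 1]))
  # orthonormal unit-variance scores
  expect_lt(max(abs(crossprod(pcs) / (n - 1) - diag(4))), 1e-8)
  expect_equal(ncol(compute_pcs(geno, 0)), 0)
  geno_mono <- cbind(geno, 1L)
  expect_warning(compute_pcs(geno_mono, 2), "monomorphic")
})

test_that("score residualization equals the direct OLS oracle", {
  set.seed(22)
  n <- 300
  pcs <- matrix(rnorm(n * 5), n, 5)
  pgs <- rnorm(n)
  adj <- residualize_pgs(pgs, pcs)
  expect_equal(mean(adj), 0, tolerance = 1e-12)
  oracle <- unname(resid(lm(pgs ~ pcs)))
  expect_lt(max(abs(adj - oracle)), 1e-10)
  # score lying in the PC span residualizes to zero
  expect_lt(max(abs(residualize_pgs(pcs[, 1], pcs))), 1e-10)
  expect_error(residualize_pgs(pgs, cbind(pcs, pcs[, 1])), "rank")
})

test_that("covariate absorption reproduces the full joint regression", {
  cfg <- sim_config(n_families = 1000, n_regions = 16, n_snps = 50,
                    h2_direct = 0.3, w_passive = 0.4, w_active = 0.2, seed = 23)
  sim <- simulate_gwas_cohort(cfg, n = 2000)
  pcs <- compute_pcs(sim$geno, 4)
  cov <- condition_covariates(sim$cohort, pcs, "current")
  ss <- assoc_scan(sim$geno, sim$cohort$pheno_ses, cov, snps = sim$snps)
  # joint-OLS oracle, one SNP at a time
  mm <- stats::model.matrix(~ . , data = cov)
  for (j in seq(1, 50, by = 7)) {
    fit <- stats::lm(sim$cohort$pheno_ses ~ sim$geno[, j] + mm - 1)
    expect_equal(ss$beta[j], unname(coef(fit)[1]), tolerance = 1e-8)
    expect_equal(ss$se[j], unname(summary(fit)$coefficients[1, 2]),
                 tolerance = 1e-8)
  }
  expect_true(all(ss$n == 2000))
  expect_equal(ss$chisq, ss$z^2)
})

test_that("region dummies absorb regional confounding in the scan", {
  cfg <- sim_config(n_families = 1500, n_regions = 16, n_snps = 80,
                    h2_direct = 0.3, w_passive = 0.5, w_active = 0.3, seed = 24)
  sim <- simulate_gwas_cohort(cfg, n = 3000)
  ses_c <- sim$layout$regions$ses[match(sim$cohort$region_current,
                                        sim$layout$regions$region)]
  # phenotype that is almost pure current-region SES: dummies leave only
  # calibrated noise, omitting them leaves inflated statistics at SNPs
  # correlated with region
  set.seed(240)
  y <- ses_c + 0.1 * rnorm(length(ses_c))
  ss_with <- assoc_scan(sim$geno, y,
                        data.frame(region = as.character(sim$cohort$region_current)))
  expect_lt(mean(ss_with$chisq), 1.35)
  ss_without <- assoc_scan(sim$geno, y)
  expect_gt(mean(ss_without$chisq), 2)
  # exactly collinear phenotype is refused, not reported as zero SEs
  expect_error(assoc_scan(sim$geno, ses_c,
                          data.frame(region = as.character(sim$cohort$region_current))),
               "zero residual")

  # reference-level choice cannot matter
  r <- as.character(sim$cohort$region_current)
  ss_a <- assoc_scan(sim$geno, sim$cohort$pheno_ses,
                     data.frame(region = factor(r)))
  ss_b <- assoc_scan(sim$geno, sim$cohort$pheno_ses,
                     data.frame(region = factor(r, levels = rev(sort(unique(r))))))
  expect_lt(max(abs(ss_a$z - ss_b$z)), 1e-10)

  # SNP duplicated as a covariate is flagged, not silently reported
  covdup <- data.frame(g1 = sim$geno[, 1])
  expect_warning(ssd <- assoc_scan(sim$geno[, 1:5], sim$cohort$pheno_ses,
                                   covdup), "collinear")
  expect_true(is.na(ssd$beta[1]))
})

test_that("per-SNP statistics stay calibrated under the null with dummies", {
  cfg <- sim_config(n_families = 1500, n_regions = 16, n_snps = 300,
                    h2_direct = 0, seed = 25)
  sim <- simulate_gwas_cohort(
    cfg, n = 3000,
    traits = list(ses = list(h2 = 0.001, var_region_birth = 0,
                             var_region_current = 0, rho_g = 1)))
  cov <- data.frame(sex = sim$cohort$sex, age = sim$cohort$age,
                    region = as.character(sim$cohort$region_current))
  ss <- assoc_scan(sim$geno, sim$cohort$pheno_ses, cov)
  expect_equal(mean(ss$chisq), 1, tolerance = 0.05)
})

test_that("incremental region R2 recovers the regional variance share", {
  set.seed(26)
  n <- 20000
  region <- sample(1:25, n, replace = TRUE)
  ses <- rnorm(25)
  ses <- (ses - mean(ses)) / sd(ses)
  y_indep <- rnorm(n)
  expect_lt(region_r2(y_indep, region)$adj_incr_r2, 0.005)
  y_pure <- ses[region]
  expect_gt(region_r2(y_pure, region)$incr_r2, 0.999)
  y_mix <- sqrt(0.2) * ses[region] + sqrt(0.8) * rnorm(n)
  expect_lt(abs(region_r2(y_mix, region)$incr_r2 - 0.2), 0.02)
  expect_equal(region_r2(y_mix, rep(1, n))$incr_r2, 0)
})

test_that("Moran's I matches its closed forms and detects smooth gradients", {
  # alternating values on a ring: perfect negative autocorrelation, exactly -1
  n <- 20
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, (i %% n) + 1] <- 1
    W[(i %% n) + 1, i] <- 1
  }
  vals <- rep(c(1, -1), n / 2)
  res <- morans_i(vals, W, n_perm = 99, seed = 1)
  expect_equal(res$I, -1, tolerance = 1e-10)

  # smooth SES gradient on the grid clusters positively
  lay <- simulate_regions(sim_config(n_regions = 36, seed = 27),
                          ses_smoothness = 1)
  res2 <- morans_i(lay$regions$ses, lay$W, n_perm = 499, seed = 2)
  expect_gt(res2$I, 0)
  expect_lt(res2$p, 0.05)

  expect_error(morans_i(rep(1, 10), diag(0, 10)), "constant")
  Wbad <- W
  Wbad[1, 2] <- 2
  expect_error(morans_i(vals, Wbad), "symmetric")
  # normal approximation agrees in direction
  res3 <- morans_i(lay$regions$ses, lay$W, method = "normal")
  expect_lt(res3$p, 0.05)
})
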