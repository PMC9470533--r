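test_that("group centering reconstructs its input exactly", {
  gc <- group_center(c(1, 3), c("f1", "f1"))
  expect_equal(gc$deviation, c(-1, 1))
  expect_equal(gc$mean, c(2, 2))
  expect_equal(group_center(rep(5, 4), rep(1:2, 2))$deviation, rep(0, 4))

  set.seed(8)
  v <- rnorm(500)
  g <- sample(letters[1:20], 500, replace = TRUE)
  gc2 <- group_center(v, g)
  expect_lt(max(abs(gc2$deviation + gc2$mean - v)), 1e-12)
  expect_lt(max(abs(tapply(gc2$deviation, g, sum))), 1e-12)

  expect_error(group_center(1:3, c("a", "", "b")), "labels")
  expect_error(group_center(1:3, c("a", NA, "b")), "labels")
})

test_that("design matrices follow the printed model formulas", {
  co <- toy_cohort()
  d2 <- build_design(co, 2)
  expect_equal(d2$terms, c("prs_w_family", "prs_b_family"))
  expect_lt(max(abs(tapply(d2$data$prs_w_family, co$fid, mean))), 1e-12)
  expect_equal(mean(d2$data$prs_w_family), 0, tolerance = 1e-12)

  # model 4 reconstruction: col1 + col2 + 2*col3 telescopes back to the score
  d4 <- build_design(co, 4)
  expect_lt(max(abs(d4$data$prs_w + d4$data$prs_bf + 2 * d4$data$prs_br -
                      co$prs)), 1e-12)

  # family alone in its region: m_k = m_j, first column collapses to the
  # family deviation minus the family mean again
  co1 <- toy_cohort()
  co1$region_current <- c(1, 1, 2, 2, 3, 3)
  d41 <- build_design(co1, 4)
  mj <- stats::ave(co1$prs, co1$fid)
  expect_equal(d41$data$prs_w, co1$prs - 2 * mj)
  expect_equal(d41$data$prs_bf, rep(0, 6))

  # single region: model 5's between column is constant and the within
  # column equals model 2's deviation column
  co2 <- toy_cohort()
  co2$region_current <- rep(1, 6)
  d5 <- build_design(co2, 5)
  d2b <- build_design(co2, 2)
  expect_equal(d5$data$prs_w_region,
               d2b$data$prs_w_family - mean(d2b$data$prs_w_family))
  expect_equal(stats::sd(d5$data$prs_b_region), 0)

  expect_error(build_design(co, 7), "unknown model")
  expect_warning(build_design(co1[1:3, ], 3), "single individual")
})

test_that("REML fixed effects collapse to OLS when variance components vanish", {
  cfg <- sim_config(n_families = 5000, n_snps = 300, h2_direct = 0.3,
                    pgs_noise = 0, var_family = 0, var_region = 0, seed = 11)
  sim <- simulate_sib_cohort(cfg)
  co <- sim$cohort
  fit <- fit_prs_model(co, "pheno", 2)
  mj <- stats::ave(co$prs, co$fid)
  ols <- stats::lm(pheno ~ I(prs - mj) + mj + sex + age, data = co)
  expect_lt(max(abs(fit$terms$estimate - unname(coef(ols)))), 1e-5)
  expect_lt(fit$varcomp[["family"]], 1e-3)

  # doubling every observation leaves estimates and shrinks SEs by ~sqrt(2)
  co2 <- dplyr::bind_rows(co, dplyr::mutate(co, fid = fid + max(fid),
                                            iid = paste0(iid, "b")))
  fit2 <- fit_prs_model(co2, "pheno", 2)
  expect_equal(fit2$terms$estimate, fit$terms$estimate, tolerance = 1e-6)
  expect_equal(fit$terms$se / fit2$terms$se, rep(sqrt(2), 5), tolerance = 0.02)
})

test_that("the null sampling distribution of the score effect is calibrated", {
  inside <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    nf <- 200
    co <- tibble::tibble(fid = rep(seq_len(nf), each = 2),
                         prs = rnorm(2 * nf), pheno = rnorm(2 * nf),
                         sex = rbinom(2 * nf, 1, 0.5),
                         age = sample(40:70, 2 * nf, TRUE))
    f <- fit_prs_model(co, "pheno", 1)
    abs(f$terms$estimate[2]) < 3 * f$terms$se[2]
  }, logical(1))
  expect_gte(mean(inside), 0.975)
})

test_that("shifting the score by a constant moves only the intercept", {
  sim <- rge_on_sim()
  co <- sim$cohort[1:2000, ]
  for (m in c(1, 2, 4, 5)) {
    f0 <- fit_prs_model(co, "pheno", m)
    co_shift <- dplyr::mutate(co, prs = prs + 3)
    f1 <- fit_prs_model(co_shift, "pheno", m)
    keep <- f0$terms$term != "(Intercept)"
    expect_equal(f1$terms$estimate[keep], f0$terms$estimate[keep],
                 tolerance = 1e-5)
  }
})

test_that("the within-family effect is immune to between-family confounding", {
  sim <- rge_off_sim()
  co <- sim$cohort
  f0 <- fit_prs_model(co, "pheno", 2)
  co2 <- co
  co2$pheno <- co$pheno + 0.5 * stats::ave(co$prs, co$fid)
  f1 <- fit_prs_model(co2, "pheno", 2)
  w <- which(f0$terms$term == "prs_w_family")
  expect_equal(f1$terms$estimate[w], f0$terms$estimate[w], tolerance = 1e-6)
  b <- which(f0$terms$term == "prs_b_family")
  expect_gt(f1$terms$estimate[b] - f0$terms$estimate[b], 0.3)
})

test_that("marginal and conditional R2 behave per their definitions", {
  sim <- rge_on_sim()
  gl <- glance(fit_prs_models(sim$cohort, "pheno", models = c(1, 4)))
  expect_true(all(gl$r2_marginal >= 0 & gl$r2_marginal <= gl$r2_conditional &
                    gl$r2_conditional <= 1))

  # fixed effects explain nothing when the response is unrelated noise
  co <- sim$cohort[1:2000, ]
  set.seed(99)
  co$noise <- rnorm(nrow(co))
  f <- fit_prs_model(co, "noise", 1)
  expect_lt(f$r2_marginal, 0.01)

  # analytic value: with a perfect score and known variances, the model-1
  # fixed effects explain h2 of the total variance
  cfg <- sim_config(n_families = 6000, n_snps = 300, h2_direct = 0.3,
                    var_family = 0.2, var_region = 0.1, pgs_noise = 0,
                    seed = 13)
  simv <- simulate_sib_cohort(cfg)
  f4 <- fit_prs_model(simv$cohort, "pheno", 4)
  # fixed effects carry h2 plus the small sex/age contributions (~0.0125)
  expect_lt(abs(f4$r2_marginal - 0.31), 0.03)
  expect_lt(abs(f4$varcomp[["family"]] / 0.2 - 1), 0.10)
  expect_lt(abs(f4$varcomp[["region"]] / 0.1 - 1), 0.12)
})

test_that("sibling-difference oracle agrees with the model-2 within effect", {
  sim <- rge_on_sim()
  f2 <- fit_prs_model(sim$cohort, "pheno", 2)
  orc <- sib_difference_oracle(sim$cohort, "pheno")
  w <- which(f2$terms$term == "prs_w_family")
  joint_se <- sqrt(f2$terms$se[w]^2 + orc$se^2)
  expect_lt(abs(f2$terms$estimate[w] - orc$estimate), 2 * joint_se)

  # pure direct effects: the oracle estimates the attenuated slope
  cfg <- sim_config(n_families = 8000, n_snps = 400, h2_direct = 0.3,
                    pgs_noise = 0.15, seed = 14)
  simd <- simulate_sib_cohort(cfg)
  orc2 <- sib_difference_oracle(simd$cohort, "pheno")
  expect_lt(abs(orc2$estimate - 0.3 / sqrt(0.3 + 0.15)), 3 * orc2$se)

  co_tied <- toy_cohort()
  co_tied$prs <- rep(1, 6)
  expect_error(sib_difference_oracle(co_tied, "pheno"), "zero")
})

test_that("model 5 separates active rGE from its absence", {
  # no active channel: within- and between-region effects estimate the same
  # quantity; count replicates where they agree within 2 joint SEs
  agree <- vapply(1:100, function(i) {
    cfg <- sim_config(n_families = 600, n_regions = 16, n_snps = 100,
                      h2_direct = 0.3, var_region = 0.1, var_family = 0.1,
                      pgs_noise = 0.1, seed = 7000 + i)
    sim <- simulate_sib_cohort(cfg)
    f5 <- fit_prs_model(sim$cohort, "pheno", 5)
    wi <- which(f5$terms$term == "prs_w_region")
    bi <- which(f5$terms$term == "prs_b_region")
    abs(f5$terms$estimate[bi] - f5$terms$estimate[wi]) <
      2 * sqrt(f5$terms$se[bi]^2 + f5$terms$se[wi]^2)
  }, logical(1))
  expect_gte(mean(agree), 0.93)

  # active channel + region effects: between-region exceeds within-region
  sim_on <- rge_on_sim()
  f5 <- fit_prs_model(sim_on$cohort, "pheno", 5)
  wi <- which(f5$terms$term == "prs_w_region")
  bi <- which(f5$terms$term == "prs_b_region")
  expect_gt(f5$terms$estimate[bi] - f5$terms$estimate[wi],
            2 * sqrt(f5$terms$se[bi]^2 + f5$terms$se[wi]^2))
})
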