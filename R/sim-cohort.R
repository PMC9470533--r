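#' Assign current regions through migration with active rGE
#'
#' Adults migrate: the SES rank of the current region follows the family's
#' standardized midparent genetic value (persistence of the birth-region
#' sorting, strength `w_passive`) plus the individual's own standardized
#' within-family genetic deviation (the active channel, strength `w_active`),
#' plus noise; the latent rank is mapped monotonically to region ids with
#' equal region sizes. With `w_active = 0`, which sibling has the higher score
#' carries no information about who lands in the higher-SES region.
#'
#' @param cohort Cohort tibble with columns `fid`, `g_true`, `midparent_g`.
#' @param layout A [simulate_regions()] layout.
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return The cohort with a `region_current` column (replaced if present).
#' @export
migrate <- function(cohort, layout, config, seed = NULL) {
  stopifnot(all(c("fid", "g_true", "midparent_g") %in% names(cohort)))
  with_seed(seed, {
    fidx <- match(cohort$fid, unique(cohort$fid))
    fam_mean <- broadcast_mean(cohort$g_true, fidx)
    dev <- cohort$g_true - fam_mean
    sd_dev <- stats::sd(dev)
    zdev <- if (sd_dev > 0) dev / sd_dev else dev * 0
    wp <- config$w_passive
    wa <- config$w_active
    zmid <- if (stats::sd(cohort$midparent_g) > 0) {
      zstd(cohort$midparent_g)
    } else rep(0, nrow(cohort))
    latent <- wp * zmid + wa * zdev +
      sqrt(1 - wp^2 - wa^2) * stats::rnorm(nrow(cohort))
    cohort$region_current <- assign_regions(latent, layout)
    cohort
  })
}

#' Simulate a phenotype with configurable rGE architecture
#'
#' Builds `Y = genetic value + delta_nurture * z(midparent) +
#' sqrt(var_region) * ses(current region) + family environment + residual`,
#' with the residual scaled so the total variance is approximately 1, then
#' adds small fixed sex and age effects (0.1 and 0.05 on the standardized
#' scale). Per-trait `overrides` replace the config's `h2_direct` (as
#' `var_direct`, the variance carried by the standardized genetic value),
#' `delta_nurture`, `var_region` and `var_family`.
#'
#' @param cohort Cohort tibble with `fid`, `g_true`, `midparent_g`, `sex`,
#'   `age`, `region_current`.
#' @param layout A [simulate_regions()] layout.
#' @param config A [sim_config()].
#' @param overrides Named list of per-trait parameter overrides (see Details).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype <- function(cohort, layout, config, overrides = list(),
                               seed = NULL) {
  par <- list(var_direct = config$h2_direct,
              delta_nurture = config$delta_nurture,
              var_region = config$var_region,
              var_family = config$var_family)
  par[names(overrides)] <- overrides
  if (par$var_direct + par$var_region + par$var_family > 1) {
    stop_invalid("variance fractions sum to more than 1")
  }
  with_seed(seed, {
    n <- nrow(cohort)
    fidx <- match(cohort$fid, unique(cohort$fid))
    nf <- max(fidx)
    K <- nrow(layout$regions)
    ses_k <- layout$regions$ses[match(cohort$region_current,
                                      layout$regions$region)] *
      sqrt(K / (K - 1))
    g <- if (stats::sd(cohort$g_true) > 0 && par$var_direct > 0) {
      sqrt(par$var_direct) * zstd(cohort$g_true)
    } else rep(0, n)
    nurt <- if (par$delta_nurture != 0 && stats::sd(cohort$midparent_g) > 0) {
      par$delta_nurture * zstd(cohort$midparent_g)
    } else rep(0, n)
    fam <- if (par$var_family > 0) {
      (sqrt(par$var_family) * stats::rnorm(nf))[fidx]
    } else rep(0, n)
    core <- g + nurt + sqrt(par$var_region) * ses_k + fam
    resid_var <- max(0.05, 1 - stats::var(core))
    core + 0.1 * cohort$sex + 0.05 * zstd(cohort$age) +
      stats::rnorm(n, 0, sqrt(resid_var))
  })
}

#' Trait menus for the synthetic cohorts
#'
#' Named lists of per-trait generative parameters spanning the qualitative
#' classes the analyses contrast: an SES-like trait (strong passive and active
#' rGE and nature-of-nurture effects), an adiposity-like trait (affected by
#' the regional environment, partially genetically correlated with the SES
#' score) and a blood-cell-like trait (direct genetic effects only).
#' `sib_trait_menu()` parameterizes [simulate_sib_cohort()];
#' `gwas_trait_menu()` parameterizes [simulate_gwas_cohort()], where
#' `var_region_birth`/`var_region_current` split the regional variance between
#' childhood and adult environments and `rho_g` is the genetic correlation of
#' the trait's SNP effects with the SES trait's effects.
#' @return A named list of per-trait parameter lists.
#' @export
sib_trait_menu <- function() {
  list(
    ses = list(var_direct = 0.20, delta_nurture = 0.15,
               var_region = 0.15, var_family = 0.15),
    adiposity = list(var_direct = 0.08, delta_nurture = 0.05,
                     var_region = 0.12, var_family = 0.10),
    bloodcell = list(var_direct = 0.15, delta_nurture = 0,
                     var_region = 0, var_family = 0.05)
  )
}

#' @rdname sib_trait_menu
#' @export
gwas_trait_menu <- function() {
  list(
    ses = list(h2 = 0.20, var_region_birth = 0.06,
               var_region_current = 0.10, rho_g = 1),
    adiposity = list(h2 = 0.20, var_region_birth = 0.02,
                     var_region_current = 0.10, rho_g = 0.35),
    bloodcell = list(h2 = 0.30, var_region_birth = 0,
                     var_region_current = 0, rho_g = 0)
  )
}

#' Simulate a sibling-pair cohort with known ground truth
#'
#' End-to-end generator for the sibling decomposition track: region layout,
#' founder couples with passive-rGE birth-region sorting, Mendelian
#' transmission of two siblings per family, migration with active rGE, the
#' (noisy-weight) polygenic score, and one phenotype column per entry of
#' `traits`.
#'
#' @param config A [sim_config()].
#' @param traits Named list of per-trait overrides for [simulate_phenotype()];
#'   the default single trait `pheno` uses the config parameters as is.
#' @param keep_genotypes Keep the sibling dosage matrix in the result
#'   (memory-heavy; the decomposition track only needs the score).
#' @param seed Seed for the whole construction (defaults to the config seed).
#' @return An object of class `sib_sim`: list with `cohort` (tibble: `fid`,
#'   `iid`, `sib`, `sex`, `age`, `region_birth`, `region_current`, `prs`
#'   (standardized), ground-truth columns `g_true`, `midparent_g`, and one
#'   `pheno_*` column per trait), `layout`, `snps`, `config`, and `geno` if
#'   kept.
#' @examples
#' sim <- simulate_sib_cohort(sim_config(n_families = 100, n_snps = 50, seed = 3))
#' head(sim$cohort)
#' @export
simulate_sib_cohort <- function(config, traits = list(pheno = list()),
                                keep_genotypes = FALSE, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    layout <- simulate_regions(config, seed = NULL)
    parents <- simulate_parents(config, layout, seed = NULL)
    sibs <- transmit_genotypes(parents, seed = NULL)
    nf <- config$n_families
    n <- 2L * nf
    prs_raw <- as.vector(sibs$geno %*% parents$snps$weight)
    g_true <- as.vector(sibs$geno %*% parents$snps$beta_true)
    cohort <- tibble::tibble(
      fid = sibs$fid,
      iid = sprintf("I%06d_%d", sibs$fid, sibs$sib),
      sib = sibs$sib,
      sex = stats::rbinom(n, 1L, 0.5),
      age = sample(40:70, n, replace = TRUE),
      region_birth = parents$couples$region_birth[sibs$fid],
      prs = if (stats::sd(prs_raw) > 0) zstd(prs_raw) else prs_raw,
      g_true = g_true,
      midparent_g = parents$couples$midparent_g[sibs$fid]
    )
    cohort <- migrate(cohort, layout, config, seed = NULL)
    for (tr in names(traits)) {
      cohort[[paste0("pheno_", tr)]] <-
        simulate_phenotype(cohort, layout, config, traits[[tr]], seed = NULL)
    }
    if (length(traits) == 1 && names(traits)[1] == "pheno") {
      names(cohort)[names(cohort) == "pheno_pheno"] <- "pheno"
    }
    cohort <- cohort[order(cohort$fid, cohort$sib), , drop = FALSE]
    out <- list(cohort = cohort, layout = layout, snps = parents$snps,
                config = config)
    if (keep_genotypes) out$geno <- sibs$geno
    class(out) <- "sib_sim"
    out
  })
}

# per-trait standardized-scale effect vectors, correlated with a base vector
make_effects <- function(M, h2, base_z = NULL, rho = 0) {
  z <- stats::rnorm(M)
  if (!is.null(base_z) && rho != 0) z <- rho * base_z + sqrt(1 - rho^2) * z
  list(z = z, beta = z * sqrt(h2 / M))
}

#' Simulate an unrelated GWAS cohort with regional rGE
#'
#' Generator for the association track: `n` unrelated individuals with
#' block-LD genotypes, one phenotype per entry of `traits` built from
#' trait-specific SNP effects (genetically correlated with the SES trait's
#' effects through `rho_g`), and birth/current regions sorted on the SES
#' trait's standardized genetic value with strengths `w_passive` (birth) and
#' `w_passive + w_active` (current, partially persistent from birth). Regional
#' SES enters each phenotype through `var_region_birth` and
#' `var_region_current`.
#'
#' @param config A [sim_config()]; `h2_direct` is ignored in favor of the
#'   per-trait `h2`.
#' @param n Number of individuals (default `2 * n_families`).
#' @param traits Named list as from [gwas_trait_menu()].
#' @param seed Seed (defaults to the config seed).
#' @return An object of class `gwas_sim`: list with `cohort` (tibble `iid`,
#'   `sex`, `age`, `region_birth`, `region_current`, `pheno_*`), `geno`
#'   (n x M integer dosages), `snps`, `layout`, `config`, and `truth`
#'   (per-trait `h2` and standardized effect vectors).
#' @export
simulate_gwas_cohort <- function(config, n = 2L * config$n_families,
                                 traits = gwas_trait_menu(),
                                 seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), "ses" %in% names(traits))
  with_seed(seed, {
    layout <- simulate_regions(config, seed = NULL)
    snps <- make_snp_map(config)
    geno <- sim_block_genotypes(n, snps)
    sdg <- sqrt(2 * snps$maf * (1 - snps$maf))
    M <- nrow(snps)
    base <- make_effects(M, traits$ses$h2)
    eff <- list(ses = base)
    for (tr in setdiff(names(traits), "ses")) {
      eff[[tr]] <- make_effects(M, traits[[tr]]$h2, base$z, traits[[tr]]$rho_g)
    }
    # genetic values on standardized-genotype scale (no per-column scaling of
    # the big matrix: divide effects instead, then center)
    gvals <- lapply(eff, function(e) {
      v <- as.vector(geno %*% (e$beta / sdg))
      v - mean(v)
    })
    zg_ses <- zstd(gvals$ses)
    wp <- config$w_passive
    wa <- config$w_active
    e_b <- stats::rnorm(n)
    latent_b <- wp * zg_ses + sqrt(1 - wp^2) * e_b
    wc <- min(0.95, wp + wa)
    persist <- 0.3
    noise_c <- sqrt(max(0.02, 1 - wc^2 - persist^2))
    latent_c <- wc * zg_ses + persist * e_b + noise_c * stats::rnorm(n)
    region_birth <- assign_regions(latent_b, layout)
    region_current <- assign_regions(latent_c, layout)
    kfac <- sqrt(nrow(layout$regions) / (nrow(layout$regions) - 1))
    ses_b <- layout$regions$ses[match(region_birth,
                                      layout$regions$region)] * kfac
    ses_c <- layout$regions$ses[match(region_current,
                                      layout$regions$region)] * kfac
    cohort <- tibble::tibble(
      iid = sprintf("G%06d", seq_len(n)),
      sex = stats::rbinom(n, 1L, 0.5),
      age = sample(40:70, n, replace = TRUE),
      region_birth = region_birth,
      region_current = region_current
    )
    truth <- list(traits = traits, effects_z = lapply(eff, `[[`, "z"))
    for (tr in names(traits)) {
      p <- traits[[tr]]
      core <- gvals[[tr]] + sqrt(p$var_region_birth) * ses_b +
        sqrt(p$var_region_current) * ses_c
      resid_var <- max(0.05, 1 - stats::var(core))
      cohort[[paste0("pheno_", tr)]] <- core + 0.1 * cohort$sex +
        0.05 * zstd(cohort$age) + stats::rnorm(n, 0, sqrt(resid_var))
    }
    structure(list(cohort = cohort, geno = geno, snps = snps, layout = layout,
                   config = config, truth = truth),
              class = "gwas_sim")
  })
}

#' @export
print.sib_sim <- function(x, ...) {
  cat(sprintf("<sib_sim> %d sibling pairs, %d regions, %d SNPs; traits: %s\n",
              x$config$n_families, nrow(x$layout$regions), nrow(x$snps),
              paste(grep("^pheno", names(x$cohort), value = TRUE),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.gwas_sim <- function(x, ...) {
  cat(sprintf("<gwas_sim> %d individuals, %d regions, %d SNPs; traits: %s\n",
              nrow(x$cohort), nrow(x$layout$regions), nrow(x$snps),
              paste(grep("^pheno", names(x$cohort), value = TRUE),
                    collapse = ", ")))
  invisible(x)
}
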