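#' Run the sibling decomposition track end to end
#'
#' For each trait: fits the requested decomposition models, runs the
#' dependent bootstrap contrast of the within effect between models 2 and 4,
#' and applies Benjamini-Hochberg FDR across traits. The output also collects
#' the model-4 between-family versus between-region comparison and the
#' model-5 within-region versus between-region comparison, the two signatures
#' of regional and active gene-environment correlation.
#'
#' @param x A [sim_config()] (a cohort is simulated with the sibling trait
#'   menu) or a `sib_sim` / cohort tibble with `pheno_*` columns.
#' @param traits Trait menu used when simulating (see [sib_trait_menu()]).
#' @param models Model ids to fit.
#' @param n_boot Bootstrap replicates for the model 2 vs 4 contrast.
#' @param alpha FDR level used for the `significant` flag.
#' @param seed Seed for the bootstrap resampling.
#' @param region_col Region column used by models 3-5.
#' @return A list of class `sibling_track`: `fits` (tidy per-term table),
#'   `summaries` (per-model fit summaries), `contrasts` (per-trait bootstrap
#'   test with `q`), `between_compare` (model-4 beta_BF vs beta_BR),
#'   `within_split` (model-5 within- vs between-region effects).
#' @export
run_sibling_track <- function(x, traits = sib_trait_menu(), models = 1:5,
                              n_boot = 500, alpha = 0.05, seed = 1L,
                              region_col = "region_current") {
  cohort <- if (inherits(x, "sim_config")) {
    simulate_sib_cohort(x, traits = traits)$cohort
  } else if (inherits(x, "sib_sim")) {
    x$cohort
  } else {
    x
  }
  trait_cols <- grep("^pheno", names(cohort), value = TRUE)
  if (!length(trait_cols)) stop_invalid("no pheno_* columns in the cohort")
  fits <- list()
  summaries <- list()
  contrasts <- list()
  for (tr in trait_cols) {
    dec <- fit_prs_models(cohort, tr, models = models,
                          region_col = region_col)
    fits[[tr]] <- tidy(dec)
    summaries[[tr]] <- glance(dec)
    if (all(c(2, 4) %in% models)) {
      contrasts[[tr]] <- tidy(bootstrap_within_diff(
        cohort, tr, n_boot = n_boot, seed = seed, region_col = region_col))
    }
  }
  fits <- dplyr::bind_rows(fits)
  summaries <- dplyr::bind_rows(summaries)
  contrasts <- if (length(contrasts)) {
    ct <- dplyr::bind_rows(contrasts)
    ct$q <- bh_fdr(ct$p)
    ct$significant <- ct$q < alpha
    ct
  } else NULL
  pick <- function(model, terms) {
    d <- fits[fits$model == model & fits$term %in% terms, ]
    tidyr::pivot_wider(d[, c("trait", "term", "estimate", "se")],
                       names_from = "term",
                       values_from = c("estimate", "se"))
  }
  between_compare <- if (4 %in% models) pick(4, c("prs_bf", "prs_br")) else NULL
  within_split <- if (5 %in% models) {
    pick(5, c("prs_w_region", "prs_b_region"))
  } else NULL
  structure(list(fits = fits, summaries = summaries, contrasts = contrasts,
                 between_compare = between_compare,
                 within_split = within_split, alpha = alpha, seed = seed),
            class = "sibling_track")
}

#' @export
print.sibling_track <- function(x, ...) {
  cat("<sibling_track>\n")
  if (!is.null(x$contrasts)) {
    cat("model 2 vs 4 within-effect contrasts:\n")
    print(as.data.frame(x$contrasts[, c("trait", "beta_w_a", "beta_w_b",
                                        "difference", "se", "p", "q")]),
          digits = 3)
  }
  invisible(x)
}

# BH across the defined p-values; undefined comparisons stay NA
bh_fdr_na <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- is.finite(p)
  if (any(ok)) q[ok] <- bh_fdr(p[ok])
  q
}

#' Covariate set for one region-correction condition
#'
#' Assembles the scan covariates -- sex, age, the supplied PC scores, and the
#' region label column(s) implied by the condition (`none`, `birth`,
#' `current`, `both`) as character columns ready for dummy coding by
#' [assoc_scan()].
#'
#' @param cohort Cohort tibble with `sex`, `age`, `region_birth`,
#'   `region_current`.
#' @param pcs PC score matrix (possibly zero columns).
#' @param condition One of `"none"`, `"birth"`, `"current"`, `"both"`.
#' @return A data frame of covariates.
#' @export
condition_covariates <- function(cohort, pcs, condition) {
  cov <- data.frame(sex = cohort$sex, age = cohort$age)
  if (ncol(pcs) > 0) cov <- cbind(cov, as.data.frame(pcs))
  if (condition %in% c("birth", "both")) {
    cov$region_birth <- as.character(cohort$region_birth)
  }
  if (condition %in% c("current", "both")) {
    cov$region_current <- as.character(cohort$region_current)
  }
  cov
}

#' Run the geography-corrected GWAS track end to end
#'
#' For each region condition (`none`, `birth`, `current`, `both`): association
#' scans for every trait with sex, age and genotype PCs as covariates plus
#' the condition's region dummy blocks; LD score regression heritability per
#' trait; genetic correlation of every other trait with the designated SES
#' trait; and dependence-aware change tests of each corrected condition
#' against `none`, FDR-corrected across traits. Regional variance-explained
#' summaries and a Moran's I clustering check of the SES trait's region means
#' are attached.
#'
#' @param x A [sim_config()] (a cohort is simulated with [gwas_trait_menu()])
#'   or a `gwas_sim`.
#' @param conditions Subset of `c("none", "birth", "current", "both")`;
#'   `"none"` is always included.
#' @param n_pcs Number of genotype PCs used as covariates.
#' @param min_region_n Minimum individuals per region level.
#' @param ses_trait Trait name whose genetic correlations are tracked.
#' @param n_blocks Jackknife blocks for LD score regression.
#' @param alpha FDR level for the `significant` flags.
#' @param keep_sumstats Keep the per-scan summary statistics in the result.
#' @return A list of class `gwas_track`: `h2`, `h2_change`, `rg`,
#'   `rg_change`, `region_r2`, `moran`, and optionally `sumstats`.
#' @export
run_gwas_track <- function(x, conditions = c("none", "birth", "current", "both"),
                           n_pcs = 10, min_region_n = 100, ses_trait = "ses",
                           n_blocks = NULL, alpha = 0.05,
                           keep_sumstats = FALSE) {
  sim <- if (inherits(x, "sim_config")) simulate_gwas_cohort(x) else x
  stopifnot(inherits(sim, "gwas_sim"))
  conditions <- union("none", match.arg(conditions,
                                        c("none", "birth", "current", "both"),
                                        several.ok = TRUE))
  cohort <- sim$cohort
  trait_cols <- grep("^pheno_", names(cohort), value = TRUE)
  traits <- sub("^pheno_", "", trait_cols)
  lds <- empirical_ld_scores(sim$geno, sim$snps$block, snps = sim$snps)
  icpt <- if (stats::sd(lds$l) == 0) "fixed" else "free"
  pcs <- compute_pcs(sim$geno, n_pcs)
  ss <- list()
  for (cond in conditions) {
    cov <- condition_covariates(cohort, pcs, cond)
    for (tr in traits) {
      ss[[paste(tr, cond, sep = ".")]] <- assoc_scan(
        sim$geno, cohort[[paste0("pheno_", tr)]], cov, snps = sim$snps,
        min_region_n = min_region_n)
    }
  }
  nb <- n_blocks %||% max(2L, min(200L, nrow(lds) %/% 10L))
  h2_fits <- lapply(ss, h2_ldsc, ldscores = lds, n_blocks = nb,
                    intercept = icpt)
  h2_tab <- dplyr::bind_rows(lapply(names(h2_fits), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    f <- h2_fits[[nm]]
    tibble::tibble(trait = parts[1], condition = parts[2], h2 = f$estimate,
                   se = f$se, intercept = f$intercept)
  }))
  h2_change <- dplyr::bind_rows(lapply(setdiff(conditions, "none"),
                                       function(cond) {
    d <- dplyr::bind_rows(lapply(traits, function(tr) {
      dt <- delta_test(h2_fits[[paste(tr, "none", sep = ".")]],
                       h2_fits[[paste(tr, cond, sep = ".")]])
      tibble::tibble(trait = tr, condition = cond, dt)
    }))
    d$q <- bh_fdr_na(d$p)
    d
  }))
  if (nrow(h2_change)) {
    h2_change$significant <- !is.na(h2_change$q) & h2_change$q < alpha
  }
  rg_fits <- list()
  other <- setdiff(traits, ses_trait)
  for (cond in conditions) {
    for (tr in other) {
      rg_fits[[paste(tr, cond, sep = ".")]] <- rg_ldsc(
        ss[[paste(tr, cond, sep = ".")]],
        ss[[paste(ses_trait, cond, sep = ".")]],
        lds, n_blocks = nb, h2_intercept = icpt)
    }
  }
  rg_tab <- dplyr::bind_rows(lapply(names(rg_fits), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    f <- rg_fits[[nm]]
    tibble::tibble(trait = parts[1], condition = parts[2],
                   rg = f$estimate, se = f$se, gencov = f$gencov)
  }))
  rg_change <- dplyr::bind_rows(lapply(setdiff(conditions, "none"),
                                       function(cond) {
    d <- dplyr::bind_rows(lapply(other, function(tr) {
      dt <- delta_test(rg_fits[[paste(tr, "none", sep = ".")]],
                       rg_fits[[paste(tr, cond, sep = ".")]])
      tibble::tibble(trait = tr, condition = cond, dt)
    }))
    d$q <- bh_fdr_na(d$p)
    d
  }))
  if (nrow(rg_change)) {
    rg_change$significant <- !is.na(rg_change$q) & rg_change$q < alpha
  }
  rr <- dplyr::bind_rows(lapply(traits, function(tr) {
    dplyr::bind_rows(lapply(c("birth", "current"), function(kind) {
      col <- paste0("region_", kind)
      tibble::tibble(trait = tr, region_kind = kind,
                     region_r2(cohort[[paste0("pheno_", tr)]],
                               cohort[[col]],
                               data.frame(sex = cohort$sex,
                                          age = cohort$age)))
    }))
  }))
  reg_mean <- tapply(cohort[[paste0("pheno_", ses_trait)]],
                     factor(cohort$region_current,
                            levels = sim$layout$regions$region),
                     mean)
  moran <- morans_i(as.vector(reg_mean), sim$layout$W, n_perm = 999, seed = 7L)
  out <- list(h2 = h2_tab, h2_change = h2_change, rg = rg_tab,
              rg_change = rg_change, region_r2 = rr, moran = moran,
              conditions = conditions, ses_trait = ses_trait, alpha = alpha)
  if (keep_sumstats) out$sumstats <- ss
  structure(out, class = "gwas_track")
}

#' @export
print.gwas_track <- function(x, ...) {
  cat("<gwas_track> SNP heritability by region condition:\n")
  print(as.data.frame(tidyr::pivot_wider(x$h2[, c("trait", "condition", "h2")],
                                         names_from = "condition",
                                         values_from = "h2")), digits = 3)
  if (nrow(x$h2_change)) {
    cat("significant h2 changes (FDR):",
        sum(x$h2_change$significant), "of", nrow(x$h2_change), "\n")
  }
  invisible(x)
}
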