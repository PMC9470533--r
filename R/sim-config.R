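#' Generative parameters for the synthetic rGE cohorts
#'
#' `sim_config()` collects every parameter of the synthetic-data generator:
#' cohort and marker sizes, the LD model, direct heritability, the strengths of
#' the passive and active gene-environment correlation (rGE) channels, and the
#' environmental variance components. The defaults describe a cohort with
#' moderate direct heritability and both rGE channels switched off; analyses
#' that need rGE turn the channels on explicitly.
#'
#' The three rGE channels are:
#' * **passive** (`w_passive`): the standardized midparent genetic value shifts
#'   the SES rank of the family's birth region, so children inherit both the
#'   alleles and the correlated rearing environment;
#' * **active** (`w_active`): an individual's own within-family genetic
#'   deviation shifts the SES rank of the region they migrate to as adults;
#' * **nature of nurture** (`delta_nurture`): the midparent genetic value
#'   affects the phenotype directly through parental behavior, independent of
#'   region.
#'
#' @param n_families Number of families (sibling pairs share two parents).
#' @param n_regions Number of geographic regions `K` (>= 2), laid out on a
#'   near-square grid with one standardized SES value per region.
#' @param n_snps Number of biallelic SNPs `M`.
#' @param ld_block_size Size `B` of exchangeable LD blocks; must divide `M`.
#'   `B = 1` gives independent SNPs.
#' @param ld_block_r Within-block pairwise genotype correlation in `[0, 1)`.
#'   May be a vector, recycled across blocks, to give heterogeneous LD (and
#'   hence non-constant LD scores).
#' @param maf_range Length-2 vector of minor allele frequency bounds in
#'   `(0, 0.5]`.
#' @param h2_direct Phenotypic variance fraction from direct additive SNP
#'   effects, in `[0, 1]`.
#' @param w_passive,w_active Passive / active rGE strengths in `[0, 1)`; see
#'   Details.
#' @param var_region Phenotypic variance contributed by the SES of the current
#'   region.
#' @param var_family Phenotypic variance contributed by a shared family
#'   environment.
#' @param delta_nurture Effect of the standardized midparent genetic value on
#'   the phenotype (nature-of-nurture path).
#' @param pgs_noise Variance of the weight-estimation noise added to the true
#'   SNP effects when forming the polygenic score; `0` gives a perfect score.
#'   With noise, the squared PGS-phenotype correlation attenuates to
#'   `h2_direct * h2_direct / (h2_direct + pgs_noise)`.
#' @param seed Integer seed; every downstream generator consumes RNG seeded
#'   from here, so equal configs reproduce bit-identical cohorts.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_families = 200, n_regions = 9, n_snps = 50, seed = 1)
#' cfg$h2_direct
#' @export
sim_config <- function(n_families = 5000,
                       n_regions = 25,
                       n_snps = 1000,
                       ld_block_size = 1,
                       ld_block_r = 0,
                       maf_range = c(0.05, 0.5),
                       h2_direct = 0.3,
                       w_passive = 0,
                       w_active = 0,
                       var_region = 0,
                       var_family = 0,
                       delta_nurture = 0,
                       pgs_noise = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families), n_regions = as.integer(n_regions),
    n_snps = as.integer(n_snps), ld_block_size = as.integer(ld_block_size),
    ld_block_r = as.numeric(ld_block_r), maf_range = as.numeric(maf_range),
    h2_direct = h2_direct, w_passive = w_passive, w_active = w_active,
    var_region = var_region, var_family = var_family,
    delta_nurture = delta_nurture, pgs_noise = pgs_noise,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_regions < 2) stop_invalid("n_regions must be >= 2")
  if (cfg$n_families < 1) stop_invalid("n_families must be >= 1")
  if (cfg$n_snps < 1) stop_invalid("n_snps must be >= 1")
  if (cfg$n_snps %% cfg$ld_block_size != 0) {
    stop_invalid("ld_block_size must divide n_snps")
  }
  if (any(cfg$ld_block_r < 0) || any(cfg$ld_block_r >= 1)) {
    stop_invalid("ld_block_r must be in [0, 1)")
  }
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop_invalid("maf_range must be an increasing pair in (0, 0.5]")
  }
  vars <- c(h2_direct = cfg$h2_direct, var_region = cfg$var_region,
            var_family = cfg$var_family, pgs_noise = cfg$pgs_noise)
  if (any(vars < 0)) stop_invalid("variance parameters must be >= 0")
  if (cfg$h2_direct > 1) stop_invalid("h2_direct must be in [0, 1]")
  if (cfg$h2_direct + cfg$var_region + cfg$var_family > 1) {
    stop_invalid("h2_direct + var_region + var_family must be <= 1")
  }
  for (w in c("w_passive", "w_active")) {
    if (cfg[[w]] < 0 || cfg[[w]] >= 1) stop_invalid(w, " must be in [0, 1)")
  }
  if (cfg$w_passive^2 + cfg$w_active^2 >= 1) {
    stop_invalid("w_passive^2 + w_active^2 must be < 1 (latent SES rank is standardized)")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  families %d, regions %d, SNPs %d (blocks of %d, r = %s)\n",
              x$n_families, x$n_regions, x$n_snps, x$ld_block_size,
              paste(signif(unique(x$ld_block_r), 3), collapse = "/")))
  cat(sprintf("  h2_direct %.2f, pgs_noise %.2f, var_region %.2f, var_family %.2f\n",
              x$h2_direct, x$pgs_noise, x$var_region, x$var_family))
  cat(sprintf("  rGE: passive %.2f, active %.2f, nurture %.2f; seed %d\n",
              x$w_passive, x$w_active, x$delta_nurture, x$seed))
  invisible(x)
}
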