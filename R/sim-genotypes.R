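#' @name genotype-simulation
#' @title Simulate founder genotypes, SNP effects and Mendelian transmission
#'
#' @description
#' Founder (parental) genotypes are drawn in Hardy-Weinberg equilibrium under a
#' block-exchangeable LD model: SNPs within a block of size `B` share one
#' allele frequency and have pairwise genotype correlation `r` exactly, built
#' by a template-copy haplotype mechanism (each haplotype copies a per-block
#' ancestral allele with probability `sqrt(r)`, otherwise draws fresh). True
#' additive effects are drawn on the standardized-genotype scale so that the
#' genetic value has variance `h2_direct` in expectation; a noisy copy of the
#' weights (variance `pgs_noise` in total) mimics out-of-sample GWAS weight
#' error and forms the polygenic score.
#'
#' Passive rGE enters at this stage: each couple's birth-region SES rank is
#' `w_passive * z(midparent genetic value) + sqrt(1 - w_passive^2) * noise`,
#' mapped monotonically to region ids with equal region sizes.
NULL

# draw an n x M dosage matrix under the block-exchangeable LD model
sim_block_genotypes <- function(n, snps) {
  M <- nrow(snps)
  geno <- matrix(0L, n, M)
  for (b in unique(snps$block)) {
    idx <- which(snps$block == b)
    p <- snps$maf[idx[1]]
    r <- snps$ld_r[idx[1]]
    B <- length(idx)
    for (h in 1:2) {
      if (r > 0 && B > 1) {
        tmpl <- stats::rbinom(n, 1L, p)
        copy <- matrix(stats::rbinom(n * B, 1L, sqrt(r)), n, B)
        fresh <- matrix(stats::rbinom(n * B, 1L, p), n, B)
        hap <- copy * tmpl + (1L - copy) * fresh
      } else {
        hap <- matrix(stats::rbinom(n * B, 1L, p), n, B)
      }
      geno[, idx] <- geno[, idx] + hap
    }
  }
  geno
}

# SNP map with per-block MAF and LD correlation, true effects and noisy weights
make_snp_map <- function(config) {
  M <- config$n_snps
  B <- config$ld_block_size
  n_blocks <- M %/% B
  maf_b <- stats::runif(n_blocks, config$maf_range[1], config$maf_range[2])
  r_b <- rep_len(config$ld_block_r, n_blocks)
  block <- rep(seq_len(n_blocks), each = B)
  maf <- maf_b[block]
  # effects on the standardized-genotype scale; Var(sum beta_std * x_std) =
  # h2_direct in expectation (exactly h2 for independent SNPs)
  beta_std <- stats::rnorm(M, 0, sqrt(config$h2_direct / M))
  weight_std <- beta_std + stats::rnorm(M, 0, sqrt(config$pgs_noise / M))
  sd_g <- sqrt(2 * maf * (1 - maf))
  tibble::tibble(
    snp = sprintf("rs%06d", seq_len(M)),
    chr = 1L,
    bp = seq_len(M) * 1000L,
    a1 = "A", a2 = "G",
    maf = maf, block = block, ld_r = r_b[block],
    beta_true = beta_std / sd_g,    # per-dosage scale
    weight = weight_std / sd_g
  )
}

#' Simulate parents with passive rGE region sorting
#'
#' Draws `2 * n_families` founder genotypes (couple `j` = mother `j` + father
#' `j`), true SNP effects and noisy polygenic-score weights, and assigns each
#' couple a birth region for their children whose SES rank follows the
#' standardized midparent genetic value with strength `w_passive`.
#'
#' @param config A [sim_config()].
#' @param layout A [simulate_regions()] layout.
#' @param seed Optional seed (defaults to the config seed).
#' @return A list of class `parent_pop`: `geno` (2`n` x `M` integer dosages,
#'   mothers then fathers), `snps` (SNP map tibble with `beta_true` and noisy
#'   `weight`), `g_value` (true genetic values), `couples` (tibble `fid`,
#'   `midparent_g`, `region_birth`).
#' @export
simulate_parents <- function(config, layout, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "region_layout"))
  with_seed(seed, {
    nf <- config$n_families
    snps <- make_snp_map(config)
    geno <- sim_block_genotypes(2L * nf, snps)
    g_value <- as.vector(geno %*% snps$beta_true)
    midparent <- (g_value[seq_len(nf)] + g_value[nf + seq_len(nf)]) / 2
    zmid <- if (stats::sd(midparent) > 0) zstd(midparent) else rep(0, nf)
    latent <- config$w_passive * zmid +
      sqrt(1 - config$w_passive^2) * stats::rnorm(nf)
    couples <- tibble::tibble(
      fid = seq_len(nf),
      midparent_g = midparent,
      region_birth = assign_regions(latent, layout)
    )
    structure(list(geno = geno, snps = snps, g_value = g_value,
                   couples = couples, role = "parent"),
              class = "parent_pop")
  })
}

#' Transmit genotypes from parent couples to sibling pairs
#'
#' Each child receives, independently per SNP and per child, one allele from
#' each parent (an allele drawn Bernoulli(dosage/2)); two siblings per family.
#' Full siblings therefore share on average half their segregating alleles,
#' giving the expected polygenic-score correlation of 0.5.
#'
#' @param parents A `parent_pop` from [simulate_parents()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A list of class `sib_geno`: `geno` (2`n_families` x `M` integer
#'   dosages, all first siblings then all second siblings), `fid`, `sib`
#'   (1 or 2), plus the parental `snps` map.
#' @export
transmit_genotypes <- function(parents, seed = NULL) {
  stopifnot(inherits(parents, "parent_pop"))
  n_par <- nrow(parents$geno)
  if (n_par %% 2 != 0) stop_invalid("parents must come in couples (even count)")
  with_seed(seed, {
    nf <- n_par %/% 2L
    M <- ncol(parents$geno)
    mom <- parents$geno[seq_len(nf), , drop = FALSE]
    dad <- parents$geno[nf + seq_len(nf), , drop = FALSE]
    draw_child <- function() {
      matrix(stats::rbinom(nf * M, 1L, as.vector(mom) / 2), nf, M) +
        matrix(stats::rbinom(nf * M, 1L, as.vector(dad) / 2), nf, M)
    }
    geno <- rbind(draw_child(), draw_child())
    structure(list(geno = geno, fid = rep(seq_len(nf), times = 2L),
                   sib = rep(1:2, each = nf), snps = parents$snps),
              class = "sib_geno")
  })
}

#' Closed-form LD scores of the block-exchangeable model
#'
#' Under blocks of size `B` with pairwise genotype correlation `r`, each SNP's
#' LD score is exactly `l_j = 1 + (B - 1) r^2` (the self term plus `B - 1`
#' neighbors at squared correlation `r^2`).
#'
#' @param config A [sim_config()].
#' @return Tibble with `snp`, `block`, `l`.
#' @examples
#' true_ld_scores(sim_config(n_snps = 20, ld_block_size = 10, ld_block_r = 0.5))$l[1]
#' # 1 + 9 * 0.25 = 3.25
#' @export
true_ld_scores <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  M <- config$n_snps
  B <- config$ld_block_size
  n_blocks <- M %/% B
  r_b <- rep_len(config$ld_block_r, n_blocks)
  block <- rep(seq_len(n_blocks), each = B)
  tibble::tibble(
    snp = sprintf("rs%06d", seq_len(M)),
    block = block,
    l = 1 + (B - 1) * r_b[block]^2
  )
}
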