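# shared small fixtures, built once per test run

# sibling cohort with all rGE channels on (used across decomp/boots tests)
rge_on_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_families = 2500, n_regions = 25, n_snps = 300, h2_direct = 0.2,
        w_passive = 0.5, w_active = 0.4, var_region = 0.15, var_family = 0.15,
        delta_nurture = 0.1, pgs_noise = 0.1, seed = 424
      )
      cache <<- simulate_sib_cohort(cfg)
    }
    cache
  }
})

# cohort with region effects in the phenotype but every rGE channel off
rge_off_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_families = 2500, n_regions = 25, n_snps = 300, h2_direct = 0.3,
        var_region = 0.15, var_family = 0.15, pgs_noise = 0.1, seed = 525
      )
      cache <<- simulate_sib_cohort(cfg)
    }
    cache
  }
})

# hand-built tiny cohort: deterministic values for exactness checks
toy_cohort <- function() {
  tibble::tibble(
    fid = rep(1:3, each = 2),
    iid = sprintf("I%d", 1:6),
    sib = rep(1:2, 3),
    sex = c(0, 1, 0, 1, 0, 1),
    age = c(50, 52, 60, 58, 45, 47),
    region_current = c(1, 1, 1, 2, 2, 2),
    prs = c(1, 3, -2, 0, 2, 4),
    pheno = c(0.5, 1.5, -1, 0, 1, 2)
  )
}
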