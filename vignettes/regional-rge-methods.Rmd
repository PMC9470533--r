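---
title: "Detecting gene-environment correlations across families and regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-environment correlations across families and regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A polygenic score predicts a trait partly through direct genetic effects and
partly through gene-environment correlations (rGE): genotypes are not
randomly distributed over environments. Two channels matter here. In the
*passive* channel, parents transmit both alleles and an environment — a
couple with a higher genetic value for educational attainment tends to raise
children in a higher-SES region. In the *active* channel, adults sort
themselves: the sibling with the higher score is more likely to migrate to a
more favorable region than their lower-scoring sibling. Both channels load
trait-associated alleles onto regional environments, so genome-wide
association statistics, SNP-based heritability and genetic correlations with
SES-related traits absorb environmental signal.

`regionrge` implements the machinery to (i) generate synthetic cohorts where
the strength of each channel is known exactly, (ii) decompose
polygenic-score associations in sibling pairs into within-family,
between-family and between-region components, (iii) test whether the
within-family effect weakens once regions are accounted for, and (iv)
re-estimate GWAS-derived heritability and genetic correlations after region
fixed effects, with change tests that honor the dependence between the
corrected and uncorrected analyses.

## The synthetic cohorts

The generator commits to the simplest mechanisms that produce all three rGE
channels with tunable strengths; every choice below is a design decision of
this package, since the analysis models themselves presuppose no particular
generative process.

**Genotypes.** `M` biallelic SNPs in Hardy-Weinberg equilibrium, organized
in exchangeable LD blocks of size `B`: within a block all SNPs share one
allele frequency (drawn from `maf_range`) and every pair has genotype
correlation `r`, constructed by a template-copy haplotype mechanism (each
haplotype copies a block-level ancestral allele with probability `sqrt(r)`).
This gives the closed form `l = 1 + (B - 1) r^2` for every LD score —
`true_ld_scores()` — which the empirical estimator is tested against.
`ld_block_r` accepts a vector (recycled over blocks) because several
analyses need LD scores that *vary* across the genome; with a single scalar
`r` all LD scores are equal and a free-intercept LD score regression is
unidentifiable (see below).

**Effects and scores.** True effects are drawn i.i.d. on the
standardized-genotype scale with total variance `h2_direct`. The analyst's
score uses *noisy* weights — true effects plus independent noise with total
variance `pgs_noise` — mimicking out-of-sample GWAS estimation error. This
gives the closed-form attenuation
`cor(PGS, Y)^2 = h2 * h2 / (h2 + pgs_noise)` used as a test oracle. A
perfect score (`pgs_noise = 0`) is used where a test needs the score to
carry the genetic value exactly (variance-component recovery).

**Families.** Couples are formed at random (no assortative mating); two
children per couple each receive one allele per SNP per parent,
independently — full siblings, expected score correlation 0.5. Transmission
is sampled per SNP given parental dosages, which breaks LD in the offspring;
the sibling track therefore defaults to independent SNPs, and LD-structured
genotypes are reserved for the unrelated GWAS cohort where LD scores matter.

**Regions.** `K` regions on a near-square grid, one standardized SES value
each (spatially smooth by default: half gradient, half noise — SES clusters
geographically, which the Moran's I diagnostic can detect), plus a
rook-adjacency matrix for spatial statistics. Sorting into regions is
rank-based: a latent SES-rank score is mapped monotonically to region ids
with equal region sizes. Birth regions follow
`w_passive * z(midparent) + noise`; current regions follow
`w_passive * z(midparent) + w_active * z(own within-family deviation) +
noise`. The midparent variable is the parents' *true* genetic value, not the
noisy score: environments respond to actual parental genotype and phenotype,
not to the analyst's weight-estimation error.

**Phenotypes.** `Y = genetic value + delta_nurture * z(midparent) +
sqrt(var_region) * ses(current region) + family environment + residual`,
with the residual scaled so total variance is approximately 1, then small
fixed sex and age effects (0.1 and 0.05). The region term is rescaled by
`sqrt(K/(K-1))` so the phenotypic variance contributed by region SES equals
`var_region` exactly under equal occupancy. The trait menus
(`sib_trait_menu()`, `gwas_trait_menu()`) span three qualitative classes —
SES-like (all channels on), adiposity-like (region-environment-affected,
genetically correlated with the SES effects at `rho_g = 0.35`), and
blood-cell-like (direct effects only) — rather than a large trait panel. The
default channel strengths for rGE-on analyses (`w_passive = 0.4`,
`w_active = 0.25` for the GWAS track; `0.5`/`0.4` for the sibling track)
were chosen once for detectability at desk-scale sample sizes; the relative
sizes of the two channels in real populations are unknown, so these are
working values, not estimates.

What the generator does *not* emulate: realistic LD from reference panels,
assortative mating, sibships larger than two, unequal region sizes,
ancestry gradients confounded with geography (the PC machinery is exercised
on explicitly structured populations in tests instead). Passing tests
therefore show that the estimators do what they claim under the stated
model, not that real data meet the model.

## The five sibling models

With `m_j` the family-mean score and `m_k` the current-region-mean score,
the fixed-effect score terms are, exactly as the models are written:

| model | score terms | random intercepts |
|---|---|---|
| 1 | `PRS` | family |
| 2 | `PRS - m_j`, `m_j` | family |
| 3 | `PRS - m_k`, `m_k` | family + region |
| 4 | `PRS - m_j - m_k`, `m_j - m_k`, `m_k` | family + region |
| 5 | `w - wbar_k`, `wbar_k` with `w = PRS - m_j` | family + region |

Sex and age enter all models as fixed covariates. Siblings can live in
different regions, so family and region intercepts are crossed, with two
separate variances; fits are REML via `lme4`. Model 4's first column
subtracts *both* means, which is not a textbook three-level centering; it is
implemented as printed, and the algebraic consequence is documented rather
than "corrected": the three columns reconstruct the score as
`col1 + col2 + 2 * col3 = PRS` (asserted exactly in the tests), and the
fixed-effect span of model 4 equals that of model 2 plus the region-mean
score. One-sided p-values are reported for the fixed effects (direction
taken from the sign of the estimate), with two-sided available by argument.
Marginal R² is `var(fixed predictor)` over the total of fixed-predictor
variance plus all variance components; conditional R² adds the family and
region intercept variances to the numerator. Pairs with a missing phenotype
in either sibling are dropped (complete-pair analysis), keeping the
within-family terms well defined. Singleton regions are retained with a
warning (their region mean equals the individual's value); a minimum
region-size filter is available where wanted.

An independent check on the within-family effect is the sibling-difference
regression — OLS of the within-pair phenotype difference on the within-pair
score difference — which estimates the same quantity through an entirely
different computation (`sib_difference_oracle()`).

## The bootstrap contrast and its null behavior

Whether the within effect weakens from model 2 to model 4 is tested by
resampling sibling pairs with replacement, re-estimating both models per
replicate with all group means recomputed inside the replicate, and using
the standard deviation of the per-replicate difference as the standard
error; `(difference / SE)^2` is referred to chi-squared with 1 degree of
freedom. Resampling pairs (not individuals) preserves the within-family
contrast; individual-level resampling is available as a sensitivity option.
Replicates where a refit fails are dropped and counted; more than 10%
failures flags the result unreliable.

Per-replicate refits use OLS for the fixed effects by default: with balanced
pairs the within-family estimator is essentially invariant to the
random-intercept weighting, and the bootstrap needs only the coefficient
difference; full REML refits (`engine = "reml"`) are orders of magnitude
slower and agree in the cases we test.

One property of the *printed* procedure deserves attention. Under a doubly
null design — no rGE *and* no regional effects on the phenotype — the
model-2 and model-4 within estimators differ only through the region-mean
score column, whose true partial coefficient is then exactly zero; the
difference is a second-order (degenerate) statistic, and the naive
n-out-of-n bootstrap overestimates the variance of such statistics, making
the chi-squared test conservative (it essentially never rejects). Under the
scientifically relevant null — regional SES *does* affect the phenotype but
no rGE channel is active, so the within effect genuinely should not change —
the difference has a first-order component and the test is well calibrated;
the suite verifies its type-I error at the 5% level under exactly that
null. Users testing traits with no regional variance at all should expect
conservative p-values from this contrast.

## Region-corrected association scans

`assoc_scan()` runs per-SNP OLS with all covariates — sex, age, genotype
PCs, and dummy blocks for any region factor (one reference level dropped) —
absorbed once by projection (Frisch-Waugh-Lovell): the phenotype and each
SNP are residualized on the covariates, and the per-SNP slope, standard
error and z equal the full joint regression's, which the tests assert to
1e-8. Region levels with fewer than `min_region_n` individuals (default
100) are removed with their individuals. PCs come from an eigendecomposition
of the standardized dosage crossproduct with a deterministic sign
convention; the synthetic analyses default to 10 PCs, since simulated
structure is low-dimensional. The cohorts here are unrelated by
construction, so OLS is correctly specified and no kinship random effect is
fitted; this is a deliberate simplification relative to mixed-model GWAS
machinery for related samples. Scans output the summary-statistic convention
`SNP A1 A2 FRQ BETA SE Z N` consumed directly by the LD score regression
module.

`region_r2()` reports the incremental (adjusted) R² of region dummies over
base covariates — how much phenotypic variation regions explain — and
`morans_i()` provides the spatial clustering diagnostic with permutation or
normal-approximation p-values.

## Heritability, genetic correlation, and change tests

LD score regression estimates SNP heritability from
`E[chi2_j] = 1 + N h2 l_j / M`: a weighted regression of per-SNP chi-squared
on LD scores, slope times `M/N`. Weights are `1/max(l, 1)` with one update
from a provisional fit — first-order heteroskedasticity weighting, not the
fully iterated scheme. The intercept is free by default (it absorbs
confounding such as uncorrected stratification); with constant LD scores the
slope and intercept are not separately identifiable, which is reported as an
error, and a constrained-intercept mode (`intercept = "fixed"`) is provided.
Genetic covariance is the slope of `z1 * z2` on the LD score scaled by
`M/sqrt(N1 N2)`, with a free intercept absorbing sample overlap; the genetic
correlation divides by the geometric mean of the heritabilities and is
reported untruncated (clipped to [-1.25, 1.25] only for display).

Standard errors come from a delete-one-block jackknife over contiguous SNP
blocks (`min(200, M/10)` by default). The per-block estimates are retained
because the central inferential step — is the corrected heritability lower
than the uncorrected one? — compares two fits of the *same sample*, whose
errors are strongly dependent. `delta_test()` jackknifes the per-block
*differences* of two fits computed on the same SNPs and blocks (mismatched
blocks are an error, never silently intersected), which prices in the
dependence; the resulting Z-test is the desk-scale analog of fitting both
estimates jointly in a structural-equation framework. For genetic
correlations, delete-one blocks where a heritability dips through zero are
stabilized by flooring the h² product at 1e-4 (the count is reported);
r_g is ill-defined in that regime regardless.

## Numerical and degenerate-input policy

Group centering reconstructs inputs exactly and errors on empty labels.
Constant scores make the sibling-difference oracle undefined (error);
constant values make Moran's I undefined (error); a phenotype exactly
collinear with the covariates is refused rather than reported with zero
standard errors. SNPs collinear with a covariate get missing statistics plus
a warning count. Non-converged or singular mixed fits are returned with
flags, not hidden. All generators are bit-reproducible given `seed`; every
stochastic analysis (bootstrap, permutation) takes its own seed.

## Problem sizes

The test suite and the reproduction script run the sibling decomposition at
up to 20,000 pairs, the bootstrap calibration at 200 replicates of 2,000
pairs with 500 bootstraps each, and the GWAS track at 6,000-10,000
individuals with 1,000-2,000 SNPs — sizes at which every qualitative
signature the package targets is comfortably detectable on a single CPU in
minutes.
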