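#' Empirical LD scores from a reference genotype panel
#'
#' For each SNP, the LD score `l_j` is the sum of squared correlations with
#' the SNPs of the same block (the self term included), each squared
#' correlation bias-corrected for reference-panel sampling noise as
#' `r2_adj = r2 - (1 - r2) / (N - 2)`. Monomorphic SNPs are dropped.
#'
#' @param geno Reference dosage matrix (N x M), N >= 50 recommended.
#' @param block Block assignment vector (length M), or a single block size
#'   used to cut SNPs into contiguous blocks.
#' @param snps Optional SNP map for ids.
#' @return Tibble `snp`, `l`.
#' @export
empirical_ld_scores <- function(geno, block, snps = NULL) {
  M <- ncol(geno)
  N <- nrow(geno)
  ids <- snps$snp %||% sprintf("rs%06d", seq_len(M))
  if (length(block) == 1) {
    block <- rep(seq_len(ceiling(M / block)), each = block)[seq_len(M)]
  }
  stopifnot(length(block) == M)
  sds <- apply(geno, 2, stats::sd)
  mono <- sds == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped from LD scoring",
            call. = FALSE)
  }
  l <- rep(NA_real_, M)
  for (b in unique(block)) {
    idx <- which(block == b & !mono)
    if (!length(idx)) next
    r2 <- stats::cor(geno[, idx, drop = FALSE])^2
    r2_adj <- r2 - (1 - r2) / (N - 2)
    l[idx] <- rowSums(r2_adj)
  }
  tibble::tibble(snp = ids[!mono], l = l[!mono])
}

# contiguous jackknife block assignment in SNP order
jackknife_blocks <- function(m, n_blocks = NULL) {
  n_blocks <- n_blocks %||% max(2L, min(200L, m %/% 10L))
  sort(rep_len(seq_len(n_blocks), m))
}

# delete-one-block weighted least squares: response y, design X (columns
# already chosen), weights w, block ids. Returns full coefficients and the
# per-block delete-one coefficient matrix.
wls_jackknife <- function(X, y, w, block) {
  Xw <- X * w
  A <- crossprod(Xw, X)
  bvec <- crossprod(Xw, y)
  full <- solve(A, bvec)
  ub <- sort(unique(block))
  loo <- matrix(NA_real_, length(ub), ncol(X))
  for (i in seq_along(ub)) {
    idx <- block == ub[i]
    Ai <- A - crossprod(Xw[idx, , drop = FALSE], X[idx, , drop = FALSE])
    bi <- bvec - crossprod(Xw[idx, , drop = FALSE], y[idx])
    loo[i, ] <- solve(Ai, bi)
  }
  list(coef = as.vector(full), loo = loo, n_blocks = length(ub))
}

jackknife_se <- function(loo) {
  B <- length(loo)
  sqrt((B - 1) / B * sum((loo - mean(loo))^2))
}

#' SNP heritability by LD score regression
#'
#' Weighted regression of the per-SNP association chi-squared statistics on
#' the LD scores: under a polygenic model, `E[chi2_j] = 1 + N h2 l_j / M` (an
#' intercept above 1 flags confounding such as uncorrected stratification), so
#' the heritability is `slope * M / N`. Heteroskedasticity weights start at
#' `1 / max(l_j, 1)` and are updated once from a provisional fit. Standard
#' errors come from a delete-one-block jackknife over contiguous SNP blocks;
#' the per-block estimates are retained so differences between fits on the
#' same blocks can be tested with [delta_test()].
#'
#' @param sumstats Summary-statistic tibble with `snp`, `z` (or `chisq`) and
#'   `n`.
#' @param ldscores Tibble `snp`, `l` (e.g. [true_ld_scores()] or
#'   [empirical_ld_scores()]).
#' @param n_blocks Number of jackknife blocks (default `min(200, M/10)`).
#' @param intercept `"free"` (default) estimates the intercept; `"fixed"`
#'   constrains it to 1, required when the LD scores are constant.
#' @return An object of class `ldsc_fit` with `estimate` (h2), `intercept`,
#'   `se`, per-block `loo` estimates, the block assignment, `M` and `N`.
#' @export
h2_ldsc <- function(sumstats, ldscores, n_blocks = NULL,
                    intercept = c("free", "fixed")) {
  intercept <- match.arg(intercept)
  d <- dplyr::inner_join(sumstats, ldscores, by = "snp")
  d <- d[stats::complete.cases(d[, c("z", "l")]), ]
  M <- nrow(d)
  if (M < 200) stop_invalid("need at least 200 SNPs for LD score regression")
  if (!"n" %in% names(d) || anyNA(d$n)) stop_invalid("missing sample size N")
  if (stats::sd(d$l) == 0 && intercept == "free") {
    stop_invalid("constant LD scores: slope and intercept are not ",
                 "separately identifiable; use intercept = \"fixed\"")
  }
  chi2 <- if ("chisq" %in% names(d)) d$chisq else d$z^2
  N <- stats::median(d$n)
  block <- jackknife_blocks(M, n_blocks)
  fit_once <- function(w) {
    if (intercept == "free") {
      wls_jackknife(cbind(1, d$l), chi2, w, block)
    } else {
      wls_jackknife(cbind(d$l), chi2 - 1, w, block)
    }
  }
  w1 <- 1 / pmax(d$l, 1)
  prov <- fit_once(w1)
  slope_prov <- prov$coef[length(prov$coef)]
  h2_prov <- max(slope_prov * M / N, 0)
  w2 <- 1 / (pmax(d$l, 1) * (1 + N * h2_prov * d$l / M)^2)
  fin <- fit_once(w2)
  k <- length(fin$coef)
  slope <- fin$coef[k]
  h2 <- slope * M / N
  loo_h2 <- fin$loo[, k] * M / N
  icpt <- if (intercept == "free") fin$coef[1] else 1
  loo_icpt <- if (intercept == "free") fin$loo[, 1] else rep(1, fin$n_blocks)
  structure(list(
    kind = "h2", estimate = h2, intercept = icpt,
    se = jackknife_se(loo_h2), se_intercept = jackknife_se(loo_icpt),
    loo = loo_h2, block = block, n_blocks = fin$n_blocks,
    M = M, N = N, snps = d$snp, intercept_mode = intercept
  ), class = "ldsc_fit")
}

#' Cross-trait genetic correlation by LD score regression
#'
#' The genetic covariance is the slope of the regression of the product of
#' the two traits' z-scores on the LD score, scaled by `M / sqrt(N1 N2)`; the
#' genetic correlation divides it by the geometric mean of the two
#' heritabilities. The intercept is left free (it absorbs sample overlap).
#' The jackknife runs over blocks shared with the two heritability fits, so
#' per-block estimates support dependence-aware change tests.
#'
#' @param sumstats1,sumstats2 Summary-statistic tibbles (`snp`, `a1`, `a2`,
#'   `z`, `n`); SNPs are intersected on id with an allele-match check
#'   (mismatches dropped with a warning).
#' @inheritParams h2_ldsc
#' @param h2_intercept Intercept mode passed to the two heritability fits;
#'   `"fixed"` also constrains the cross-trait regression's intercept to 0
#'   (no sample overlap), which is required when the LD scores are constant.
#' @return An `ldsc_fit` of kind `"rg"` with `estimate` (r_g), `gencov`, the
#'   two h2 fits, jackknife `se` and per-block `loo`. Flagged `undefined` if
#'   either heritability is non-positive.
#' @export
rg_ldsc <- function(sumstats1, sumstats2, ldscores, n_blocks = NULL,
                    h2_intercept = c("free", "fixed")) {
  h2_intercept <- match.arg(h2_intercept)
  d <- dplyr::inner_join(sumstats1, sumstats2, by = "snp",
                         suffix = c("_1", "_2"))
  if (all(c("a1_1", "a1_2", "a2_1", "a2_2") %in% names(d))) {
    mism <- d$a1_1 != d$a1_2 | d$a2_1 != d$a2_2
    if (any(mism)) {
      warning(sum(mism), " SNP(s) with mismatched alleles dropped",
              call. = FALSE)
      d <- d[!mism, ]
    }
  }
  d <- dplyr::inner_join(d, ldscores, by = "snp")
  d <- d[stats::complete.cases(d[, c("z_1", "z_2", "l")]), ]
  M <- nrow(d)
  if (M < 200) stop_invalid("need at least 200 shared SNPs")
  N1 <- stats::median(d$n_1)
  N2 <- stats::median(d$n_2)
  block <- jackknife_blocks(M, n_blocks)
  ss1 <- tibble::tibble(snp = d$snp, z = d$z_1, n = d$n_1)
  ss2 <- tibble::tibble(snp = d$snp, z = d$z_2, n = d$n_2)
  lds <- tibble::tibble(snp = d$snp, l = d$l)
  nb <- length(unique(block))
  fit1 <- h2_ldsc(ss1, lds, n_blocks = nb, intercept = h2_intercept)
  fit2 <- h2_ldsc(ss2, lds, n_blocks = nb, intercept = h2_intercept)
  h1 <- fit1$estimate
  h2 <- fit2$estimate
  # weights from the provisional per-trait fits
  a1 <- N1 * max(h1, 0.001) * d$l / M + 1
  a2 <- N2 * max(h2, 0.001) * d$l / M + 1
  w <- 1 / (pmax(d$l, 1) * a1 * a2)
  y <- d$z_1 * d$z_2
  if (stats::sd(d$l) == 0 && h2_intercept == "free") {
    stop_invalid("constant LD scores: use h2_intercept = \"fixed\"")
  }
  fin <- if (h2_intercept == "free") {
    wls_jackknife(cbind(1, d$l), y, w, block)
  } else {
    wls_jackknife(cbind(d$l), y, w, block)
  }
  k <- length(fin$coef)
  gencov <- fin$coef[k] * M / sqrt(N1 * N2)
  loo_gencov <- fin$loo[, k] * M / sqrt(N1 * N2)
  undefined <- h1 <= 0 || h2 <= 0
  rg <- if (undefined) NA_real_ else gencov / sqrt(h1 * h2)
  # per-block ratios: the heritability product is floored at a small positive
  # value so delete-one blocks where an h2 dips through zero do not poison the
  # jackknife (r_g is ill-defined there anyway; the count is reported)
  hprod <- fit1$loo * fit2$loo
  n_floored <- sum(hprod < 1e-4)
  loo_rg <- loo_gencov / sqrt(pmax(hprod, 1e-4))
  se <- if (undefined) NA_real_ else jackknife_se(loo_rg)
  structure(list(
    kind = "rg", estimate = rg, gencov = gencov,
    intercept = if (h2_intercept == "free") fin$coef[1] else 0, se = se,
    loo = loo_rg, loo_gencov = loo_gencov, block = block,
    n_blocks = fin$n_blocks, M = M, N = c(N1 = N1, N2 = N2),
    h2_1 = fit1, h2_2 = fit2, undefined = undefined,
    n_floored_blocks = n_floored,
    snps = d$snp
  ), class = "ldsc_fit")
}

#' Dependence-aware test for a change in h2 or r_g
#'
#' Two LD score regression fits computed on the same SNPs and the same
#' jackknife blocks (e.g. a trait's heritability from the uncorrected scan
#' and from the region-corrected scan of the same sample) have highly
#' dependent sampling errors. The change test therefore jackknifes the
#' per-block *differences*: `SE` of the difference comes from the delete-one
#' differences, honoring the dependence, and `Z = (A - B) / SE` is referred
#' to a standard normal (two-sided).
#'
#' @param fitA,fitB `ldsc_fit` objects of the same kind computed on the same
#'   block assignment; mismatched blocks are an error, never silently
#'   intersected.
#' @return One-row tibble: `estimate_a`, `estimate_b`, `delta`, `se`, `z`,
#'   `p`.
#' @export
delta_test <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "ldsc_fit"), inherits(fitB, "ldsc_fit"))
  if (fitA$kind != fitB$kind) stop_invalid("fits are of different kinds")
  if (fitA$n_blocks != fitB$n_blocks ||
      length(fitA$snps) != length(fitB$snps) ||
      !all(fitA$snps == fitB$snps) || !all(fitA$block == fitB$block)) {
    stop_invalid("fits must share the same SNPs and block assignment")
  }
  delta <- fitA$estimate - fitB$estimate
  d_loo <- fitA$loo - fitB$loo
  if (anyNA(d_loo)) stop_invalid("undefined per-block estimates in the fits")
  se <- jackknife_se(d_loo)
  if (se == 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / se
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  tibble::tibble(kind = fitA$kind, estimate_a = fitA$estimate,
                 estimate_b = fitB$estimate, delta = delta, se = se,
                 z = z, p = p)
}

#' @export
print.ldsc_fit <- function(x, ...) {
  if (x$kind == "h2") {
    cat(sprintf("<ldsc_fit> h2 = %.4f (jackknife SE %.4f), intercept %.3f\n",
                x$estimate, x$se, x$intercept))
  } else {
    cat(sprintf("<ldsc_fit> r_g = %.4f (jackknife SE %.4f), gencov %.4f%s\n",
                x$estimate, x$se, x$gencov,
                if (isTRUE(x$undefined)) " [undefined: non-positive h2]" else ""))
  }
  cat(sprintf("  M = %d SNPs, %d jackknife blocks\n", x$M, x$n_blocks))
  invisible(x)
}

#' @rdname tidy.prs_fit
#' @method tidy ldsc_fit
#' @export
tidy.ldsc_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, estimate = x$estimate, se = x$se,
    intercept = x$intercept,
    # display convention: clip r_g to [-1.25, 1.25]; the estimate itself is
    # reported untruncated
    display = if (x$kind == "rg" && is.finite(x$estimate)) {
      max(-1.25, min(1.25, x$estimate))
    } else x$estimate,
    M = x$M, n_blocks = x$n_blocks
  )
}

#' @rdname tidy.prs_fit
#' @method glance ldsc_fit
#' @export
glance.ldsc_fit <- function(x, ...) tidy(x, ...)
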