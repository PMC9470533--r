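#' Genotype principal components
#'
#' PCA of the column-standardized dosage matrix via an eigendecomposition of
#' the smaller crossproduct, returning unit-variance scores with a
#' deterministic sign convention (the largest-magnitude SNP loading of each
#' component is positive). Monomorphic SNPs are dropped with a warning.
#'
#' @param geno n x M dosage matrix (0/1/2).
#' @param n_pcs Number of components; `0` returns a zero-column matrix.
#' @return n x `n_pcs` matrix of scores, columns `PC1` ...; attribute `sdev`
#'   holds the singular values.
#' @export
compute_pcs <- function(geno, n_pcs = 10) {
  n <- nrow(geno)
  if (n_pcs == 0) return(matrix(numeric(0), n, 0))
  sds <- apply(geno, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " monomorphic SNP(s) dropped before PCA",
            call. = FALSE)
    geno <- geno[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(geno) < n_pcs || n < n_pcs) {
    stop_invalid("need at least n_pcs SNPs and individuals")
  }
  X <- scale(geno)
  if (ncol(X) <= n) {
    ed <- eigen(crossprod(X), symmetric = TRUE)
    V <- ed$vectors[, seq_len(n_pcs), drop = FALSE]
    scores <- X %*% V
    d <- sqrt(pmax(ed$values[seq_len(n_pcs)], 0))
  } else {
    ed <- eigen(tcrossprod(X), symmetric = TRUE)
    scores <- ed$vectors[, seq_len(n_pcs), drop = FALSE] %*%
      diag(sqrt(pmax(ed$values[seq_len(n_pcs)], 0)), n_pcs)
    d <- sqrt(pmax(ed$values[seq_len(n_pcs)], 0))
    V <- crossprod(X, scores) %*% diag(1 / pmax(d, 1e-12)^2, n_pcs)
  }
  for (j in seq_len(n_pcs)) {
    if (V[which.max(abs(V[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  scores <- scale(scores)
  dimnames(scores) <- list(NULL, paste0("PC", seq_len(n_pcs)))
  attr(scores, "sdev") <- d / sqrt(n - 1)
  attr(scores, "scaled:center") <- NULL
  attr(scores, "scaled:scale") <- NULL
  scores
}

#' Regress principal components out of a polygenic score
#'
#' OLS residual of the score on an intercept plus the supplied PCs, the
#' population-stratification control applied to scores before any sibling
#' analysis; the result has mean zero.
#'
#' @param pgs Numeric score vector.
#' @param pcs Matrix (or data frame) of PC scores, rows aligned with `pgs`.
#' @return Residualized score vector.
#' @export
residualize_pgs <- function(pgs, pcs) {
  pcs <- as.matrix(pcs)
  if (nrow(pcs) != length(pgs)) stop_invalid("pgs and pcs are misaligned")
  X <- cbind(1, pcs)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop_invalid("PC block is rank deficient")
  as.vector(qr.resid(qx, pgs))
}

# build the absorbed covariate matrix: intercept + numeric columns + dummy
# blocks for factor/character columns (reference level dropped), applying the
# min-region-n filter to each factor. Returns list(C, keep_rows, dropped).
build_covariate_matrix <- function(covariates, n, min_level_n = 0) {
  if (is.null(covariates)) {
    return(list(C = matrix(1, n, 1), keep = rep(TRUE, n), dropped = 0L))
  }
  covariates <- as.data.frame(covariates)
  keep <- rep(TRUE, n)
  dropped <- 0L
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v)) {
      tab <- table(v)
      bad <- names(tab)[tab < min_level_n]
      if (length(bad)) {
        keep <- keep & !(as.character(v) %in% bad)
      }
    }
  }
  dropped <- sum(!keep)
  if (dropped) {
    message(dropped, " individual(s) dropped from levels below the ",
            "minimum group size")
  }
  covariates <- covariates[keep, , drop = FALSE]
  blocks <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) < 2) return(NULL)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, levels(f)[-1])
      mm
    } else {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, nm))
      m
    }
  })
  C <- cbind(`(Intercept)` = rep(1, nrow(covariates)),
             do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))]))
  list(C = C, keep = keep, dropped = dropped)
}

#' Association scan with absorbed covariates
#'
#' Per-SNP ordinary least squares where all covariates -- sex, age, PCs and
#' any region dummy blocks -- are absorbed once by projection
#' (Frisch-Waugh-Lovell): phenotype and each SNP are residualized on the
#' covariates and the per-SNP slope on the residualized genotype equals the
#' SNP coefficient of the full joint regression, with the matching joint-OLS
#' standard error. Character or factor covariate columns become dummy blocks
#' with one reference level dropped; levels with fewer than `min_region_n`
#' individuals are removed (with the individuals) before scanning.
#'
#' @param geno n x M dosage matrix.
#' @param pheno Numeric phenotype vector.
#' @param covariates Optional data frame of covariates (numeric columns used
#'   as is; character/factor columns dummy-coded).
#' @param snps Optional SNP map tibble (`snp`, `a1`, `a2`, ...) for the
#'   output annotation.
#' @param min_region_n Minimum individuals per factor level (applied per
#'   factor column).
#' @return Tibble in summary-statistic convention: `snp`, `a1`, `a2`, `frq`,
#'   `beta`, `se`, `z`, `chisq`, `n`. SNPs collinear with the covariates are
#'   returned with missing statistics and counted in a warning.
#' @export
assoc_scan <- function(geno, pheno, covariates = NULL, snps = NULL,
                       min_region_n = 0) {
  n <- nrow(geno)
  if (length(pheno) != n) stop_invalid("phenotype and genotypes misaligned")
  cc <- stats::complete.cases(pheno) &
    (if (is.null(covariates)) TRUE else stats::complete.cases(covariates))
  cov_cc <- if (is.null(covariates)) NULL else
    as.data.frame(covariates)[cc, , drop = FALSE]
  bc <- build_covariate_matrix(cov_cc, sum(cc), min_region_n)
  rows <- which(cc)[bc$keep]
  y <- pheno[rows]
  G <- geno[rows, , drop = FALSE]
  C <- bc$C
  qx <- qr(C)
  if (qx$rank < ncol(C)) {
    C <- C[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(C)
  }
  yr <- qr.resid(qx, y)
  if (sum(yr^2) < 1e-12) stop_invalid("zero residual phenotype variance")
  Gr <- G - qr.fitted(qx, G)
  gtg <- colSums(Gr^2)
  gty <- as.vector(crossprod(Gr, yr))
  yty <- sum(yr^2)
  dfree <- length(y) - ncol(C) - 1
  bad <- gtg < 1e-10
  beta <- se <- rep(NA_real_, ncol(G))
  beta[!bad] <- gty[!bad] / gtg[!bad]
  rss <- yty - beta^2 * gtg
  se[!bad] <- sqrt(pmax(rss[!bad], 0) / dfree / gtg[!bad])
  if (any(bad)) {
    warning(sum(bad), " SNP(s) collinear with the covariates; statistics ",
            "set to missing", call. = FALSE)
  }
  z <- beta / se
  tibble::tibble(
    snp = snps$snp %||% sprintf("rs%06d", seq_len(ncol(G))),
    a1 = snps$a1 %||% rep("A", ncol(G)),
    a2 = snps$a2 %||% rep("G", ncol(G)),
    frq = colMeans(G) / 2,
    beta = beta, se = se, z = z, chisq = z^2,
    n = length(y)
  )
}

#' Variance explained by region membership
#'
#' Incremental R-squared (raw and adjusted) of adding region dummy variables
#' to a base covariate model for a phenotype -- the regional
#' variance-explained summary used to gauge geographic clustering of a trait.
#'
#' @param pheno Numeric phenotype.
#' @param regions Region labels.
#' @param covariates Optional base covariate data frame.
#' @return One-row tibble: `r2_base`, `r2_region`, `incr_r2`, `adj_incr_r2`,
#'   `n`, `n_regions`.
#' @export
region_r2 <- function(pheno, regions, covariates = NULL) {
  cc <- stats::complete.cases(pheno, regions) &
    (if (is.null(covariates)) TRUE else stats::complete.cases(covariates))
  y <- pheno[cc]
  f <- factor(regions[cc])
  if (nlevels(f) < 2) {
    return(tibble::tibble(r2_base = NA_real_, r2_region = NA_real_,
                          incr_r2 = 0, adj_incr_r2 = 0, n = length(y),
                          n_regions = nlevels(f)))
  }
  base_df <- if (is.null(covariates)) {
    data.frame(y = y)
  } else {
    data.frame(y = y, as.data.frame(covariates)[cc, , drop = FALSE])
  }
  fit0 <- stats::lm(y ~ ., data = base_df)
  fit1 <- stats::lm(y ~ . + f, data = cbind(base_df, f = f))
  s0 <- summary(fit0)
  s1 <- summary(fit1)
  tibble::tibble(
    r2_base = s0$r.squared, r2_region = s1$r.squared,
    incr_r2 = s1$r.squared - s0$r.squared,
    adj_incr_r2 = s1$adj.r.squared - s0$adj.r.squared,
    n = length(y), n_regions = nlevels(f)
  )
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / sum(W)) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the
#' centered values, together with a permutation p-value (values permuted over
#' units) or a normal approximation. Used here to check geographic clustering
#' of region-level quantities (SES, mean scores, principal components).
#'
#' @param values Numeric vector, one per spatial unit; must not be constant.
#' @param weights Symmetric spatial weight matrix with zero diagonal.
#' @param n_perm Number of permutations (ignored for `method = "normal"`).
#' @param method `"permutation"` (default) or `"normal"`.
#' @param alternative `"greater"` (default; clustering), `"less"` or
#'   `"two.sided"`.
#' @param seed Optional seed for the permutations.
#' @return One-row tibble: `I`, `expected` (`-1/(n-1)`), `p`, `n`, `n_perm`.
#' @export
morans_i <- function(values, weights, n_perm = 999,
                     method = c("permutation", "normal"),
                     alternative = c("greater", "less", "two.sided"),
                     seed = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 3) stop_invalid("need at least 3 spatial units")
  weights <- as.matrix(weights)
  if (!isTRUE(all.equal(weights, t(weights)))) {
    stop_invalid("weights must be symmetric")
  }
  if (any(diag(weights) != 0)) stop_invalid("weights must have zero diagonal")
  if (stats::sd(values) == 0) stop_invalid("Moran's I undefined for constant values")
  s0 <- sum(weights)
  stat <- function(v) {
    z <- v - mean(v)
    (n / s0) * as.numeric(t(z) %*% weights %*% z) / sum(z^2)
  }
  I <- stat(values)
  e_i <- -1 / (n - 1)
  p <- if (method == "permutation") {
    perms <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) stat(sample(values)), numeric(1))
    })
    switch(alternative,
      greater = (1 + sum(perms >= I)) / (n_perm + 1),
      less = (1 + sum(perms <= I)) / (n_perm + 1),
      two.sided = min(1, 2 * min((1 + sum(perms >= I)) / (n_perm + 1),
                                 (1 + sum(perms <= I)) / (n_perm + 1)))
    )
  } else {
    # moments under the randomization (permutation) distribution
    z <- values - mean(values)
    s1 <- 0.5 * sum((weights + t(weights))^2)
    s2 <- sum((rowSums(weights) + colSums(weights))^2)
    b2 <- n * sum(z^4) / sum(z^2)^2
    var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
                b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_i^2
    zz <- (I - e_i) / sqrt(var_i)
    switch(alternative,
      greater = stats::pnorm(zz, lower.tail = FALSE),
      less = stats::pnorm(zz),
      two.sided = 2 * stats::pnorm(abs(zz), lower.tail = FALSE)
    )
  }
  tibble::tibble(I = I, expected = e_i, p = p, n = n,
                 n_perm = if (method == "permutation") n_perm else NA_integer_)
}
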