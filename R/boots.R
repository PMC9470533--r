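#' Dependent-coefficient bootstrap test for the change in the within effect
#'
#' The within-family effect of the score is estimated twice on the same data
#' (by default in model 2, family decomposition only, and in model 4, family
#' plus region decomposition), so the two estimates are strongly dependent and
#' their difference cannot be tested from the two marginal standard errors. A
#' significantly weaker within effect in model 4 than in model 2 indicates
#' gene-environment correlations that extend beyond the family across regions.
#' Sampling units (sibling pairs by default) are resampled with replacement to
#' the original size; both models are re-estimated in each replicate with all
#' group means recomputed within the replicate; the standard deviation of the
#' per-replicate difference is the bootstrap SE. Any correlation between the
#' two coefficients is reproduced faithfully across replicates, so the SE of
#' the difference accounts for it. The test statistic
#' `(difference / SE)^2` is chi-squared with 1 degree of freedom under the
#' null.
#'
#' The default engine re-estimates the fixed effects of each replicate by OLS:
#' with balanced sibling pairs the within-family estimator is essentially
#' invariant to the random-intercept weighting, and only the fixed-effect
#' difference is resampled. `engine = "reml"` refits the full mixed models
#' (orders of magnitude slower).
#'
#' @param cohort Sibling cohort tibble.
#' @param trait Response column name.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed for the resampling.
#' @param models Length-2 vector of model ids to contrast (within term of the
#'   first minus within term of the second is reported as `a - b` with
#'   `a = models[1]`).
#' @param engine `"ols"` (default) or `"reml"`.
#' @param unit Resampling unit: `"family"` (default; keeps the within-family
#'   contrast intact) or `"individual"` (sensitivity option).
#' @param prs_col,region_col Column names.
#' @param return_replicates Keep the per-replicate coefficient pairs in the
#'   result (matrix `replicates` with columns `beta_a`, `beta_b`), useful for
#'   diagnosing the dependence the test exploits.
#' @return An object of class `rge_diff_test` with the two within estimates,
#'   their difference, bootstrap SE, chi-squared statistic, p-value, replicate
#'   counts and an `unreliable` flag when more than 10% of replicates failed.
#' @export
bootstrap_within_diff <- function(cohort, trait, n_boot = 1000, seed = 1L,
                                  models = c(2L, 4L),
                                  engine = c("ols", "reml"),
                                  unit = c("family", "individual"),
                                  prs_col = "prs",
                                  region_col = "region_current",
                                  return_replicates = FALSE) {
  engine <- match.arg(engine)
  unit <- match.arg(unit)
  if (n_boot < 100) stop_invalid("n_boot must be >= 100")
  stopifnot(length(models) == 2)
  keep <- stats::complete.cases(cohort[[trait]])
  fid_ok <- names(which(table(cohort$fid[keep]) == 2))
  cohort <- cohort[keep & cohort$fid %in% fid_ok, , drop = FALSE]
  if (nrow(cohort) == 0) stop_invalid("no complete sibling pairs with this trait")
  cohort <- cohort[order(cohort$fid), , drop = FALSE]
  n <- nrow(cohort)
  nf <- n %/% 2L
  prs <- cohort[[prs_col]]
  y <- cohort[[trait]]
  sex <- as.numeric(cohort$sex)
  age <- as.numeric(cohort$age)
  region <- cohort[[region_col]]
  fidx <- rep(seq_len(nf), each = 2L)
  ridx <- match(region, sort(unique(region)))

  point <- vapply(models, function(m) {
    beta_within(prs, y, sex, age, fidx, ridx, m, engine = engine)
  }, numeric(1))
  diff_point <- point[1] - point[2]

  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      if (unit == "family") {
        f <- sample.int(nf, nf, replace = TRUE)
        rows <- as.vector(rbind(2L * f - 1L, 2L * f))
        fidx_b <- fidx
      } else {
        rows <- sample.int(n, n, replace = TRUE)
        fidx_b <- match(fidx[rows], unique(fidx[rows]))
      }
      ridx_b <- match(ridx[rows], sort(unique(ridx[rows])))
      b1 <- beta_within(prs[rows], y[rows], sex[rows], age[rows], fidx_b,
                        ridx_b, models[1], engine = engine)
      b2 <- beta_within(prs[rows], y[rows], sex[rows], age[rows], fidx_b,
                        ridx_b, models[2], engine = engine)
      c(b1, b2)
    }, numeric(2))
  })
  diffs <- reps[1, ] - reps[2, ]
  failed <- sum(!is.finite(diffs))
  diffs <- diffs[is.finite(diffs)]
  se <- stats::sd(diffs)
  chisq <- (diff_point / se)^2
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(list(
    trait = trait, models = models,
    beta_w_a = point[1], beta_w_b = point[2],
    difference = diff_point, se = se, chisq = chisq, p = p,
    n_boot = n_boot, n_failed = failed,
    unreliable = failed > 0.1 * n_boot,
    seed = as.integer(seed), engine = engine, unit = unit,
    replicates = if (return_replicates) {
      matrix(t(reps), ncol = 2, dimnames = list(NULL, c("beta_a", "beta_b")))
    } else NULL
  ), class = "rge_diff_test")
}

# within-coefficient of one decomposition model; OLS fast path or REML
beta_within <- function(prs, y, sex, age, fidx, ridx, model,
                        engine = "ols") {
  gmean <- function(x, idx) {
    cnt <- tabulate(idx)
    (rowsum(x, idx, reorder = TRUE) / cnt[cnt > 0])[idx]
  }
  mj <- gmean(prs, fidx)
  X <- switch(as.character(model),
    "1" = cbind(1, prs, sex, age),
    "2" = cbind(1, prs - mj, mj, sex, age),
    "3" = {
      mk <- gmean(prs, ridx)
      cbind(1, prs - mk, mk, sex, age)
    },
    "4" = {
      mk <- gmean(prs, ridx)
      cbind(1, prs - mj - mk, mj - mk, mk, sex, age)
    },
    "5" = {
      w <- prs - mj
      wk <- gmean(w, ridx)
      cbind(1, w - wk, wk, sex, age)
    },
    stop_invalid("unknown model id: ", model)
  )
  if (engine == "ols") {
    fit <- stats::.lm.fit(X, y)
    if (fit$rank < ncol(X)) return(NA_real_)
    co <- fit$coefficients
    co[order(fit$pivot)][2]
  } else {
    df <- data.frame(y = y, X[, -1, drop = FALSE], fid = fidx, region = ridx)
    names(df)[2] <- "x_within"
    rand <- if (model %in% 1:2) "(1 | fid)" else "(1 | fid) + (1 | region)"
    fixed <- paste(setdiff(names(df), c("y", "fid", "region")),
                   collapse = " + ")
    fit <- try(suppressWarnings(suppressMessages(
      lme4::lmer(stats::as.formula(paste("y ~", fixed, "+", rand)), data = df,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    )), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    unname(lme4::fixef(fit)["x_within"])
  }
}

#' @export
print.rge_diff_test <- function(x, ...) {
  cat(sprintf("<rge_diff_test> trait '%s', within effect model %d vs %d\n",
              x$trait, x$models[1], x$models[2]))
  cat(sprintf("  beta_W%d = %.4f, beta_W%d = %.4f, diff = %.4f (boot SE %.4f)\n",
              x$models[1], x$beta_w_a, x$models[2], x$beta_w_b, x$difference,
              x$se))
  cat(sprintf("  chi2(1) = %.3f, p = %.3g (%d bootstraps, %d failed%s)\n",
              x$chisq, x$p, x$n_boot, x$n_failed,
              if (x$unreliable) "; UNRELIABLE" else ""))
  invisible(x)
}

#' @rdname tidy.prs_fit
#' @method tidy rge_diff_test
#' @export
tidy.rge_diff_test <- function(x, ...) {
  tibble::tibble(trait = x$trait,
                 model_a = x$models[1], model_b = x$models[2],
                 beta_w_a = x$beta_w_a, beta_w_b = x$beta_w_b,
                 difference = x$difference, se = x$se,
                 chisq = x$chisq, p = x$p,
                 n_boot = x$n_boot, n_failed = x$n_failed,
                 unreliable = x$unreliable)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjusted p-values; monotone nondecreasing in
#' the input p-values and invariant to input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`; no missing values.
#' @return Vector of q-values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(!is.finite(pvalues))) {
    stop_invalid("p-values must be finite and non-missing")
  }
  if (any(pvalues < 0 | pvalues > 1)) stop_invalid("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
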