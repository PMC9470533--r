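#' Center values within groups
#'
#' Splits a numeric predictor into its deviation from the group mean and the
#' group mean broadcast back to each row, the building block of every
#' within/between decomposition here. Deviation plus mean reconstructs the
#' input exactly, and deviations sum to zero within every group.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; must contain no missing values.
#' @return Tibble with `deviation` and `mean`.
#' @examples
#' group_center(c(1, 3), c("f1", "f1"))
#' @export
group_center <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop_invalid("values and groups must have equal length")
  }
  if (anyNA(groups) || any(!nzchar(as.character(groups)))) {
    stop_invalid("groups must be non-missing, non-empty labels")
  }
  g <- match(groups, unique(groups))
  m <- broadcast_mean(values, g)
  tibble::tibble(deviation = values - m, mean = m)
}

# model-id -> human description, used in printing
MODEL_LABELS <- c(
  "1" = "individual-level score",
  "2" = "within + between family",
  "3" = "within + between region",
  "4" = "within + between family + between region",
  "5" = "within-family split into within and between region"
)

#' Build the fixed-effect design of sibling decomposition models 1-5
#'
#' Constructs the polygenic-score columns of the five models literally, with
#' `m_j` the family mean score and `m_k` the region mean score:
#' * model 1: `PRS`
#' * model 2: `(PRS - m_j, m_j)`
#' * model 3: `(PRS - m_k, m_k)`
#' * model 4: `(PRS - m_j - m_k, m_j - m_k, m_k)`
#' * model 5: with `w = PRS - m_j`: `(w - wbar_k, wbar_k)`
#'
#' Model 4's first column subtracts both means as printed, so the exact
#' reconstruction identity is `col1 + col2 + 2 * col3 = PRS`. Sex and age are
#' appended as fixed covariates. Models 1-2 carry a family random intercept;
#' models 3-5 carry crossed family and region random intercepts.
#'
#' @param cohort Cohort tibble with the score, `fid`, sex/age and (for models
#'   3-5) a region column.
#' @param model Model id in 1..5.
#' @param prs_col,region_col,sex_col,age_col Column names in `cohort`.
#' @return A list of class `prs_design`: `data` (tibble with the response-free
#'   design: score terms, `sex`, `age`, `fid`, `region`), `terms` (names of
#'   the score columns), `model`, `random` (grouping factors used).
#' @export
build_design <- function(cohort, model, prs_col = "prs",
                         region_col = "region_current",
                         sex_col = "sex", age_col = "age") {
  if (!model %in% 1:5) stop_invalid("unknown model id: ", model)
  prs <- cohort[[prs_col]]
  if (is.null(prs)) stop_invalid("missing score column '", prs_col, "'")
  fam <- group_center(prs, cohort$fid)
  terms <- switch(as.character(model),
    "1" = tibble::tibble(prs = prs),
    "2" = tibble::tibble(prs_w_family = fam$deviation, prs_b_family = fam$mean),
    "3" = , "4" = , "5" = {
      region <- cohort[[region_col]]
      if (is.null(region)) {
        stop_invalid("model ", model, " needs region column '", region_col, "'")
      }
      reg <- group_center(prs, region)
      if (model == 3) {
        tibble::tibble(prs_w_region = reg$deviation, prs_b_region = reg$mean)
      } else if (model == 4) {
        tibble::tibble(prs_w = prs - fam$mean - reg$mean,
                       prs_bf = fam$mean - reg$mean,
                       prs_br = reg$mean)
      } else {
        w <- fam$deviation
        wk <- group_center(w, region)
        tibble::tibble(prs_w_region = wk$deviation, prs_b_region = wk$mean)
      }
    }
  )
  random <- if (model %in% 1:2) "fid" else c("fid", "region")
  data <- terms
  data$sex <- cohort[[sex_col]]
  data$age <- cohort[[age_col]]
  data$fid <- cohort$fid
  if (model >= 3) {
    region <- cohort[[region_col]]
    if (any(tabulate(match(region, unique(region))) == 1)) {
      warning("region(s) with a single individual: region mean equals the ",
              "individual value there", call. = FALSE)
    }
    data$region <- region
  }
  structure(list(data = data, terms = names(terms), model = model,
                 random = random),
            class = "prs_design")
}

#' Fit one sibling polygenic-score decomposition model
#'
#' Fits the random-intercept mixed model of the given design by REML
#' (family intercept for models 1-2; crossed family and region intercepts for
#' models 3-5) and reports fixed effects with standard errors, t-values and
#' one-sided p-values (direction taken from the sign of the estimate, the
#' reporting convention of the sibling analyses), the variance components,
#' and marginal / conditional R-squared.
#'
#' @inheritParams build_design
#' @param trait Name of the response column in `cohort`.
#' @param p_sided `"one"` (default) or `"two"`.
#' @param keep_fit Keep the underlying `lmerMod` object.
#' @param ... Passed to [build_design()].
#' @return An object of class `prs_fit`; see [tidy.prs_fit()] and
#'   [glance.prs_fit()].
#' @export
fit_prs_model <- function(cohort, trait, model, prs_col = "prs",
                          region_col = "region_current",
                          p_sided = c("one", "two"), keep_fit = FALSE, ...) {
  p_sided <- match.arg(p_sided)
  y <- cohort[[trait]]
  if (is.null(y)) stop_invalid("missing trait column '", trait, "'")
  keep <- stats::complete.cases(y)
  # complete-pair analysis: drop the whole pair when one sibling is missing
  fid_ok <- names(which(table(cohort$fid[keep]) == 2))
  keep <- keep & cohort$fid %in% fid_ok
  if (!any(keep)) stop_invalid("no complete sibling pairs with this trait")
  cohort <- cohort[keep, , drop = FALSE]
  y <- y[keep]
  design <- build_design(cohort, model, prs_col = prs_col,
                         region_col = region_col, ...)
  df <- design$data
  df$.y <- y
  fixed <- paste(c(design$terms, "sex", "age"), collapse = " + ")
  rand <- paste(sprintf("(1 | %s)", design$random), collapse = " + ")
  form <- stats::as.formula(paste(".y ~", fixed, "+", rand))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  singular <- lme4::isSingular(fit)
  converged <- length(fit@optinfo$conv$lme4) == 0
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- est / se
  p <- if (p_sided == "one") stats::pnorm(abs(tval), lower.tail = FALSE) else
    2 * stats::pnorm(abs(tval), lower.tail = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v[1] else 0
  }
  varcomp <- c(family = getv("fid"), region = getv("region"),
               residual = getv("Residual"))
  pred_fixed <- as.vector(stats::model.matrix(fit) %*% est)
  out <- list(
    model = model, trait = trait,
    terms = tibble::tibble(term = names(est), estimate = unname(est),
                           se = unname(se), t = unname(tval), p = unname(p)),
    prs_terms = design$terms,
    varcomp = varcomp,
    var_fixed = stats::var(pred_fixed),
    converged = converged, singular = singular,
    logLik = as.numeric(stats::logLik(fit)),
    n = nrow(df), n_families = length(unique(df$fid)),
    p_sided = p_sided
  )
  r2 <- r2_marginal_conditional(out)
  out$r2_marginal <- r2[["r2_marginal"]]
  out$r2_conditional <- r2[["r2_conditional"]]
  if (keep_fit) out$fit <- fit
  class(out) <- "prs_fit"
  out
}

#' Marginal and conditional R-squared of a decomposition fit
#'
#' `R2_marginal = var(fixed predictor) / (var(fixed) + s2_family + s2_region +
#' s2_residual)`; the conditional version adds the random-intercept variances
#' to the numerator. Marginal R-squared is the variance explained by the fixed
#' effects only, conditional by fixed and random effects together.
#'
#' @param fit A `prs_fit`.
#' @return Named numeric vector `r2_marginal`, `r2_conditional`.
#' @export
r2_marginal_conditional <- function(fit) {
  tot <- fit$var_fixed + sum(fit$varcomp)
  if (tot <= 0) stop_invalid("zero total variance")
  c(r2_marginal = fit$var_fixed / tot,
    r2_conditional = (fit$var_fixed + fit$varcomp[["family"]] +
                        fit$varcomp[["region"]]) / tot)
}

#' Fit all requested decomposition models for one trait
#'
#' @inheritParams fit_prs_model
#' @param models Integer vector of model ids.
#' @return A list of class `prs_decomp` of `prs_fit` objects, named
#'   `model1` ... ; [tidy()] stacks the per-term tables, [glance()] the fit
#'   summaries.
#' @export
fit_prs_models <- function(cohort, trait, models = 1:5, ...) {
  fits <- lapply(models, function(m) fit_prs_model(cohort, trait, m, ...))
  names(fits) <- paste0("model", models)
  structure(fits, class = "prs_decomp", trait = trait)
}

#' Within-family slope from sibling differences (independent oracle)
#'
#' Ordinary least squares of the within-pair phenotype difference on the
#' within-pair score difference (with sex and age differences as covariates,
#' no intercept), which estimates the same within-family estimand as model 2's
#' deviation term but through an entirely different computation. Pairs with a
#' missing phenotype are dropped.
#'
#' @param cohort Sibling cohort tibble (two siblings per family).
#' @param trait Response column name.
#' @param prs_col Score column name.
#' @return Tibble with `estimate`, `se`, `t`, `n_pairs`.
#' @export
sib_difference_oracle <- function(cohort, trait, prs_col = "prs") {
  d <- cohort[order(cohort$fid, cohort$sib %||% seq_len(nrow(cohort))), ]
  d <- d[stats::complete.cases(d[[trait]]), ]
  ok <- names(which(table(d$fid) == 2))
  d <- d[d$fid %in% ok, ]
  i1 <- !duplicated(d$fid)
  i2 <- duplicated(d$fid)
  dy <- d[[trait]][i1] - d[[trait]][i2]
  dp <- d[[prs_col]][i1] - d[[prs_col]][i2]
  dsex <- d$sex[i1] - d$sex[i2]
  dage <- d$age[i1] - d$age[i2]
  if (all(dp == 0)) stop_invalid("all within-pair score differences are zero")
  fit <- stats::lm(dy ~ 0 + dp + dsex + dage)
  sm <- summary(fit)$coefficients
  tibble::tibble(estimate = sm["dp", 1], se = sm["dp", 2], t = sm["dp", 3],
                 n_pairs = length(dy))
}

#' @export
print.prs_fit <- function(x, ...) {
  cat(sprintf("<prs_fit> model %d (%s), trait '%s', n = %d (%d families)\n",
              x$model, MODEL_LABELS[[as.character(x$model)]], x$trait, x$n,
              x$n_families))
  print(as.data.frame(x$terms), digits = 3)
  cat(sprintf("variance components: family %.4f, region %.4f, residual %.4f\n",
              x$varcomp[["family"]], x$varcomp[["region"]],
              x$varcomp[["residual"]]))
  cat(sprintf("marginal R2 %.4f, conditional R2 %.4f%s%s\n",
              x$r2_marginal, x$r2_conditional,
              if (x$singular) " [singular]" else "",
              if (!x$converged) " [non-convergence]" else ""))
  invisible(x)
}

#' Tidy methods for decomposition fits
#'
#' `tidy()` returns one row per fixed-effect term (`estimate`, `se`, `t`,
#' `p`); `glance()` returns a one-row fit summary with variance components,
#' marginal and conditional R-squared and convergence flags. On a
#' `prs_decomp` both stack across models with a `model` column.
#'
#' @param x A `prs_fit` or `prs_decomp`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy prs_fit
#' @export
tidy.prs_fit <- function(x, ...) {
  tibble::tibble(model = x$model, trait = x$trait, x$terms)
}

#' @rdname tidy.prs_fit
#' @method glance prs_fit
#' @export
glance.prs_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, trait = x$trait,
    r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional,
    var_family = x$varcomp[["family"]], var_region = x$varcomp[["region"]],
    var_residual = x$varcomp[["residual"]],
    logLik = x$logLik, n = x$n, n_families = x$n_families,
    converged = x$converged, singular = x$singular
  )
}

#' @rdname tidy.prs_fit
#' @method tidy prs_decomp
#' @export
tidy.prs_decomp <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy))
}

#' @rdname tidy.prs_fit
#' @method glance prs_decomp
#' @export
glance.prs_decomp <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), glance))
}

#' @export
print.prs_decomp <- function(x, ...) {
  cat(sprintf("<prs_decomp> trait '%s', models %s\n", attr(x, "trait"),
              paste(vapply(unclass(x), `[[`, 1, "model"), collapse = ", ")))
  print(as.data.frame(glance(x)), digits = 3)
  invisible(x)
}
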