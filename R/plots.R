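#' Plot methods for decomposition and track results
#'
#' `autoplot()` methods return ggplot objects: fixed-effect estimates with
#' 95% confidence intervals across models for a `prs_decomp`; the model-2
#' versus model-4 within-effect comparison for a `sibling_track`; and
#' SNP heritability by region-correction condition for a `gwas_track`.
#'
#' @param object The fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @method autoplot prs_decomp
#' @export
autoplot.prs_decomp <- function(object, ...) {
  d <- tidy(object)
  d <- d[grep("^prs", d$term), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$se,
      ymax = .data$estimate + 1.96 * .data$se)) +
    ggplot2::facet_wrap(~model, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "estimate (95% CI)",
                  title = paste("Score decomposition:", attr(object, "trait"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @method autoplot sibling_track
#' @export
autoplot.sibling_track <- function(object, ...) {
  d <- object$contrasts
  if (is.null(d)) stop_invalid("no model 2 vs 4 contrasts in this track")
  rng <- range(c(d$beta_w_a, d$beta_w_b))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_w_a, y = .data$beta_w_b,
                                  color = .data$significant)) +
    ggplot2::geom_abline(linetype = 2, color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$trait), vjust = -1,
                       size = 3, show.legend = FALSE) +
    ggplot2::coord_equal(xlim = rng, ylim = rng) +
    ggplot2::labs(x = "within effect, model 2 (family only)",
                  y = "within effect, model 4 (family + region)",
                  color = "FDR significant") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @method autoplot gwas_track
#' @export
autoplot.gwas_track <- function(object, ...) {
  d <- object$h2
  d$condition <- factor(d$condition,
                        levels = c("none", "birth", "current", "both"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$h2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$h2 - 1.96 * .data$se,
                                        ymax = .data$h2 + 1.96 * .data$se),
                           width = 0.25) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "region correction", y = "SNP heritability (95% CI)") +
    ggplot2::theme_minimal()
}

#' Map of the simulated region layout
#'
#' Tile map of the per-region SES values on the simulation grid.
#'
#' @param layout A `region_layout`.
#' @return A ggplot object.
#' @export
plot_region_layout <- function(layout) {
  ggplot2::ggplot(layout$regions,
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$ses)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$region), size = 3) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "SES") +
    ggplot2::theme_minimal()
}
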