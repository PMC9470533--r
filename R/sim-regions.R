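#' Simulate a geographic region layout with SES values
#'
#' Places `K = n_regions` regions on a near-square grid, draws one standardized
#' socio-economic status (SES) value per region, and builds the rook-adjacency
#' weight matrix used by spatial statistics. SES is spatially smooth by
#' default (a diagonal gradient plus noise), emulating the geographic
#' clustering of deprivation that motivates region fixed effects; regions
#' otherwise act purely as categorical labels.
#'
#' @param config A [sim_config()].
#' @param ses_smoothness Fraction of SES variance carried by the grid gradient
#'   (0 = spatially unstructured SES).
#' @param seed Optional seed; defaults to the config seed.
#' @return An object of class `region_layout`: a list with
#'   * `regions`: tibble with `region` (1..K), `ses` (mean 0, variance 1),
#'     grid coordinates `x`, `y`;
#'   * `W`: symmetric K x K rook-adjacency 0/1 matrix with zero diagonal.
#' @examples
#' lay <- simulate_regions(sim_config(n_regions = 9, seed = 2))
#' colMeans(lay$regions["ses"])  # 0 by construction
#' @export
simulate_regions <- function(config, ses_smoothness = 0.5, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_regions
  if (K < 2) stop_invalid("n_regions must be >= 2")
  with_seed(seed, {
    nr <- floor(sqrt(K))
    nc <- ceiling(K / nr)
    x <- ((seq_len(K) - 1) %% nc) + 1
    y <- ((seq_len(K) - 1) %/% nc) + 1
    grad <- x + y
    raw <- if (K > 2 && stats::sd(grad) > 0 && ses_smoothness > 0) {
      sqrt(ses_smoothness) * zstd(grad) + sqrt(1 - ses_smoothness) * stats::rnorm(K)
    } else {
      stats::rnorm(K)
    }
    ses <- zstd(raw, "region ses")
    W <- matrix(0, K, K)
    for (i in seq_len(K)) {
      nb <- which(abs(x - x[i]) + abs(y - y[i]) == 1)
      W[i, nb] <- 1
    }
    out <- list(
      regions = tibble::tibble(region = seq_len(K), ses = ses, x = x, y = y),
      W = W
    )
    class(out) <- "region_layout"
    out
  })
}

#' @export
print.region_layout <- function(x, ...) {
  cat(sprintf("<region_layout> %d regions on a %d x %d grid\n",
              nrow(x$regions), max(x$regions$y), max(x$regions$x)))
  print(utils::head(x$regions, 4))
  invisible(x)
}

# Map a continuous latent SES-rank score to region ids: equal-size rank bins,
# bin b -> region with b-th smallest SES (monotone map).
assign_regions <- function(latent, layout) {
  K <- nrow(layout$regions)
  n <- length(latent)
  rk <- rank(latent, ties.method = "first")
  bin <- ceiling(rk * K / n)
  ord <- order(layout$regions$ses)
  layout$regions$region[ord][bin]
}
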