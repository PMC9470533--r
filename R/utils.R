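# internal helpers shared across modules

# evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# standardize to mean 0, sd 1 (sample sd); errors on constant input
zstd <- function(x, what = "values") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize constant ", what, call. = FALSE)
  }
  (x - mean(x)) / s
}

# group means broadcast back to each row; `g` an integer index in 1..n_groups
broadcast_mean <- function(x, g, n_groups = max(g)) {
  cnt <- tabulate(g, nbins = n_groups)
  sums <- rowsum(x, g, reorder = TRUE)
  means <- as.vector(sums) / cnt[sort(unique(g))]
  full <- rep(NA_real_, n_groups)
  full[sort(unique(g))] <- means
  full[g]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}
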