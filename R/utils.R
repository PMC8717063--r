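#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed plus a sequence of integer indices
#' (pair, participant, run, purpose, ...) to a new seed in `[1, 2^31 - 2]`.
#' Every source of randomness in the package draws its seed through this
#' splitter, so each participant/run stream is reproducible on its own and
#' independent streams never share a seed by construction of the hash.
#'
#' @param seed master integer seed.
#' @param ... further non-negative integer indices identifying the stream.
#' @return a single integer seed.
#' @export
split_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (v in as.numeric(idx)) {
    # 64-bit safe modular mix: doubles hold integers exactly below 2^53
    h <- (h * 48271 + (v %% m) + 11) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-wise Pearson correlation of two matrices
#'
#' Correlates row `v` of `a` with row `v` of `b` (same voxel, two
#' participants). Zero-variance rows yield `NA`.
#'
#' @param a,b numeric matrices of identical dimension (voxels x observations).
#' @return numeric vector of correlations, length `nrow(a)`.
#' @export
row_correlation <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  row_pearson_cpp(a, b)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}
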