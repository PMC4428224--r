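# Internal helpers shared across stages.

# Column variances without building a full covariance matrix.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to compute a variance")
  mu <- colMeans(x)
  colSums(sweep(x, 2L, mu)^2) / (n - 1L)
}

# Deterministic per-subject RNG streams: the first k draws from the master
# seed are stable no matter how many subjects follow, so adding a subject
# never perturbs existing subjects' data.
spawn_seeds <- function(master_seed, n, offset = 0L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(bitwXor(as.integer(master_seed), as.integer(offset)))
  sample.int(2147483646L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Exact ">= p/q" comparison for a retention fraction: converts the numeric
# threshold to a small rational so that counts sitting exactly on the
# boundary (e.g. 5 of 100 at 5%) are retained without float surprises.
frac_ge <- function(numerator, denominator, threshold) {
  stopifnot(denominator > 0L)
  for (q in 1:10000) {
    p <- round(threshold * q)
    if (abs(p / q - threshold) < 1e-12) {
      return(as.numeric(numerator) * q >= p * as.numeric(denominator))
    }
  }
  numerator / denominator >= threshold
}

# Polynomial rolling hash of a character vector; used for config
# fingerprints in run manifests. All intermediates stay below 2^53 so the
# result is exact and platform-stable.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Upper-triangle (i < j) index pairs of an n x n matrix, ordered by column
# then row -- the canonical global edge order.
upper_tri_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
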