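# Internal helpers: seeded evaluation and deterministic per-subject RNG streams.

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Stable 31-bit string hash (polynomial rolling hash), so per-subject RNG
# streams depend on the subject id, never on subject order.
str_hash31 <- function(x) {
  vapply(x, function(s) {
    codes <- utf8ToInt(s)
    h <- 0
    for (cc in codes) h <- (h * 31 + cc) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Derive a subject-level seed from a cohort-level seed and a subject id.
derive_seed <- function(seed, id) {
  as.integer((as.numeric(seed) + as.numeric(str_hash31(as.character(id)))) %%
               2147483647)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

stopifnot_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

# Column means/variances for a subjects x features matrix without matrixStats.
col_vars <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

# Upper-triangle (i < j) index pairs of an n x n matrix, column-major order.
upper_tri_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}
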