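# Shared fixtures, built in code at test time.

# Small cohort parameters for fast end-to-end exercises.
small_params <- function(seed = 42, ...) {
  args <- list(...)
  base <- list(n_ptx = 12, n_notx = 6, n_nodes = 20,
               planted_edges = data.frame(i = c(2L, 5L), j = c(9L, 13L),
                                          dz = c(0.3, -0.3),
                                          persistent = c(TRUE, FALSE)),
               seed = seed)
  for (nm in names(args)) base[nm] <- list(args[[nm]])  # NULL-safe override
  do.call(cohort_params, base)
}

# Standard six-visit schedule used across tests.
test_visits <- function() as.Date("2015-01-05") + cumsum(c(0, 14, 14, 7, 14, 7))

# Label a cohort's ratings with periods.
label_cohort_ratings <- function(cohort) {
  vd <- test_visits()
  out <- do.call(rbind, lapply(split(cohort$ratings, cohort$ratings$subject_id),
                               function(x) suppressMessages(assign_periods(x, vd))))
  rownames(out) <- NULL
  out
}

# Independent oracle: exhaustive enumeration of the two-sample permutation
# test (pooled t, two-sided, ties count as exceeding). Small samples only.
exhaustive_perm_p <- function(baseline, treatment) {
  pooled <- c(baseline, treatment)
  n1 <- length(baseline)
  t_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    if (sp2 <= 0) return(0)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  t_obs <- t_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  t_all <- apply(combos, 2, t_of)
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# Independent oracle: textbook Pearson chi-squared on a 2x2 table.
chi2_by_hand <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}
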