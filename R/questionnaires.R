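# Questionnaire subscales: generic scoring with the >20%-missing rule and
# within-subscale mean imputation, training-set-only normalization, and the
# Bonferroni univariate screen against response labels and magnitude.

#' Score a questionnaire subscale with the missing-data rule
#'
#' If more than 20% of a subscale's items are missing the subscale is not
#' scored; otherwise missing items are replaced with the mean of the
#' answered items *within the subscale* and the items are aggregated.
#'
#' @param item_responses numeric vector of item responses, `NA` = skipped.
#' @param n_items number of items the subscale has (defaults to
#'   `length(item_responses)`).
#' @param rule aggregation rule, `"sum"` (default) or `"mean"`.
#' @param max_missing maximum tolerated missing fraction (default 0.2).
#' @return scalar score, or `NA` if unscorable.
#' @export
score_subscale <- function(item_responses, n_items = length(item_responses),
                           rule = c("sum", "mean"), max_missing = 0.2) {
  rule <- match.arg(rule)
  n_items <- stopifnot_count(n_items, "n_items", min = 1L)
  x <- as.numeric(item_responses)
  if (length(x) != n_items)
    stop("length(item_responses) must equal n_items", call. = FALSE)
  n_miss <- sum(is.na(x))
  if (n_miss == n_items || n_miss / n_items > max_missing)
    return(NA_real_)
  if (n_miss > 0L) x[is.na(x)] <- mean(x, na.rm = TRUE)
  switch(rule, sum = sum(x), mean = mean(x))
}

#' Z-score features with training-set statistics only
#'
#' Centers and scales a subjects-by-features matrix using means and SDs
#' computed from a designated training set, and applies those same
#' statistics to held-out rows -- the leakage-safe normalization used
#' throughout the cross-validated models.
#'
#' @param train numeric matrix/data frame of training subjects.
#' @param test optional matrix of held-out subjects, normalized with the
#'   *training* statistics.
#' @return list with `train`, `test` (or `NULL`), `center`, `scale`.
#'   Zero-SD features are centered but left unscaled (scale 1).
#' @export
normalize_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  te <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    te <- sweep(sweep(test, 2, ctr), 2, scl, "/")
  }
  list(train = tr, test = te, center = ctr, scale = scl)
}

#' Univariate screen of subscales against response
#'
#' For every subscale: a two-sample t test between responders and
#' non-responders, and a Pearson correlation with the magnitude of response
#' (%analgesia). Subjects that are outliers on magnitude (beyond
#' `outlier_k` SD, see [exclude_outliers()]) are excluded first.
#' Significance is flagged at the Bonferroni level `alpha / m_comparisons`.
#'
#' @param scores subjects x subscales numeric matrix or data frame.
#' @param labels responder labels (`"Responder"` / `"NonResponder"`).
#' @param magnitude per-subject %analgesia (same order as rows).
#' @param m_comparisons Bonferroni divisor (default 37).
#' @param alpha familywise level (default 0.05).
#' @param outlier_k SD multiple for the magnitude outlier exclusion.
#' @return data frame, one row per subscale: group-difference `t` and
#'   `p_group`, correlation `r` and `p_cor`, the Bonferroni `threshold`,
#'   logical flags `sig_group`, `sig_cor`, and `untestable` for constant
#'   subscales.
#' @export
univariate_screen <- function(scores, labels, magnitude, m_comparisons = 37,
                              alpha = 0.05, outlier_k = 3) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels),
            nrow(scores) == length(magnitude))
  keep <- exclude_outliers(magnitude, k = outlier_k)
  scores <- scores[keep, , drop = FALSE]
  labels <- labels[keep]
  magnitude <- magnitude[keep]
  grp <- labels == "Responder"
  if (sum(grp) < 3L || sum(!grp) < 3L)
    stop("need at least 3 subjects per group after outlier exclusion",
         call. = FALSE)
  thr <- alpha / m_comparisons
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    x <- scores[, j]
    ok <- !is.na(x)
    if (sd(x[ok]) == 0 || sum(ok & grp) < 2L || sum(ok & !grp) < 2L)
      return(data.frame(subscale = colnames(scores)[j], t = NA_real_,
                        p_group = NA_real_, r = NA_real_, p_cor = NA_real_,
                        sig_group = FALSE, sig_cor = FALSE,
                        untestable = TRUE, stringsAsFactors = FALSE))
    tt <- t.test(x[ok & grp], x[ok & !grp], var.equal = TRUE)
    ct <- cor.test(x[ok], magnitude[ok])
    data.frame(subscale = colnames(scores)[j],
               t = unname(tt$statistic), p_group = tt$p.value,
               r = unname(ct$estimate), p_cor = ct$p.value,
               sig_group = tt$p.value < thr, sig_cor = ct$p.value < thr,
               untestable = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  attr(out, "n_subjects") <- nrow(scores)
  attr(out, "n_excluded_outliers") <- sum(!keep)
  out
}
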