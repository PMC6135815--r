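# Ecological momentary assessment (EMA) outcomes: cleaning of app-based VAS
# pain ratings, permutation-based responder stratification, response
# magnitude / %analgesia, effect sizes and response-rate contrasts.

#' Remove near-duplicate app ratings
#'
#' Ratings entered within 30 minutes of each other are treated as
#' reassessments: within any run of entries pairwise-chained closer than the
#' window, only the final entry is kept, taken as the subject's final
#' assessment at that time. Gaps are never interpolated or resampled.
#'
#' The scan is sequential, left to right: each entry is compared with the
#' current candidate; if it falls within the window it replaces the
#' candidate, otherwise the candidate is committed. A run of closely spaced
#' entries therefore collapses to its last member.
#'
#' @param ratings data frame with columns `timestamp` (POSIXct) and `vas`
#'   (numeric, 0--10). May carry additional columns, which are preserved.
#' @param window_min duplicate window in minutes (default 30).
#' @return the input data frame, time-sorted, with duplicates removed.
#' @examples
#' t0 <- as.POSIXct("2024-01-01 10:00:00", tz = "UTC")
#' x <- data.frame(timestamp = t0 + c(0, 25, 40) * 60, vas = c(6, 5, 4))
#' dedupe_ratings(x) # keeps only the 10:40 entry
#' @export
dedupe_ratings <- function(ratings, window_min = 30) {
  stopifnot(is.data.frame(ratings),
            all(c("timestamp", "vas") %in% names(ratings)))
  if (nrow(ratings) == 0L) return(ratings)
  ratings <- ratings[order(ratings$timestamp), , drop = FALSE]
  keep <- logical(nrow(ratings))
  cand <- 1L
  if (nrow(ratings) > 1L) {
    for (i in 2L:nrow(ratings)) {
      dt <- as.numeric(difftime(ratings$timestamp[i], ratings$timestamp[cand],
                                units = "mins"))
      if (dt < window_min) {
        cand <- i               # reassessment: later entry supersedes
      } else {
        keep[cand] <- TRUE
        cand <- i
      }
    }
  }
  keep[cand] <- TRUE
  out <- ratings[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label ratings with trial periods from visit dates
#'
#' Assigns each rating to the half-open interval `[visit_k, visit_{k+1})` it
#' falls in, labelling the five intervals between six visits as baseline
#' (BL), first treatment (T1), first washout (W1), second treatment (T2) and
#' second washout (W2). Entries before visit 1 or at/after visit 6 are
#' dropped with a message.
#'
#' @param ratings data frame with a `timestamp` column (POSIXct or Date).
#' @param visit_dates six strictly increasing dates/datetimes.
#' @return `ratings` restricted to in-trial entries with a `period` column.
#' @export
assign_periods <- function(ratings, visit_dates) {
  if (length(visit_dates) < 2L)
    stop("at least 2 visit dates are required", call. = FALSE)
  vd <- as.POSIXct(visit_dates, tz = "UTC")
  if (any(diff(as.numeric(vd)) <= 0))
    stop("visit dates must be strictly increasing", call. = FALSE)
  labels <- c("BL", "T1", "W1", "T2", "W2")[seq_len(length(vd) - 1L)]
  ts <- as.POSIXct(ratings$timestamp, tz = "UTC")
  bin <- findInterval(as.numeric(ts), as.numeric(vd),
                      rightmost.closed = FALSE)
  inside <- bin >= 1L & bin <= length(labels)
  n_drop <- sum(!inside)
  if (n_drop > 0L)
    message(sprintf("assign_periods: dropped %d rating(s) outside the trial window",
                    n_drop))
  out <- ratings[inside, , drop = FALSE]
  out$period <- labels[bin[inside]]
  rownames(out) <- NULL
  out
}

#' Within-subject permutation test for diminution of pain
#'
#' Tests a subject's baseline ratings against one treatment period's ratings
#' with a two-sample pooled-variance t statistic whose null distribution is
#' generated by randomly reshuffling the period labels over the pooled
#' ratings. The p value is the fraction of shuffles with `|t*| >= |t|`
#' (two-sided; ties count as exceeding) with the add-one correction
#' `(b + 1) / (n_perm + 1)` so that p is never exactly zero.
#'
#' @param baseline numeric vector of baseline-period VAS ratings.
#' @param treatment numeric vector of treatment-period VAS ratings.
#' @param n_perm number of label reshuffles (default 10000).
#' @param seed integer seed; the test is reproducible given the seed.
#' @param alternative `"two.sided"` (default) or `"less"` (diminution only).
#' @return list with elements `t` (observed statistic, baseline minus
#'   treatment orientation: positive t means lower pain under treatment),
#'   `p`, and `n_perm`.
#' @export
permutation_response_test <- function(baseline, treatment, n_perm = 10000,
                                      seed = 1L,
                                      alternative = c("two.sided", "less")) {
  alternative <- match.arg(alternative)
  baseline <- as.numeric(baseline); treatment <- as.numeric(treatment)
  if (length(baseline) < 2L || length(treatment) < 2L)
    stop("both periods need at least 2 ratings", call. = FALSE)
  n_perm <- stopifnot_count(n_perm, "n_perm", min = 1L)

  pooled <- c(baseline, treatment)
  n1 <- length(baseline); n <- length(pooled)
  t_obs <- pooled_t(baseline, treatment)
  if (is.na(t_obs)) {               # zero variance in both, equal means
    return(list(t = 0, p = 1, n_perm = n_perm))
  }

  t_null <- with_seed(seed, {
    # membership matrix: n x n_perm, TRUE marks "baseline" assignment
    vapply(seq_len(n_perm), function(i) {
      g <- sample.int(n, n1)
      pooled_t(pooled[g], pooled[-g])
    }, numeric(1))
  })
  t_null[is.na(t_null)] <- 0
  b <- if (alternative == "two.sided") sum(abs(t_null) >= abs(t_obs))
       else sum(t_null >= t_obs)
  list(t = t_obs, p = (b + 1) / (n_perm + 1), n_perm = n_perm)
}

# Pooled-variance two-sample t, oriented so that lower treatment pain gives
# positive t. NA when both groups are constant and equal.
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  d <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (d == 0) return(NA_real_)
    return(sign(d) * Inf)
  }
  d / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Stratify a subject as placebo responder or non-responder
#'
#' Runs the within-subject permutation test of baseline against each
#' treatment period. The subject is a responder if at least one treatment
#' period shows a significant diminution in pain -- that is, `p < alpha`
#' *and* the treatment mean is below the baseline mean. A significant
#' increase never counts as response.
#'
#' @param baseline,t1,t2 numeric VAS rating vectors; `t1`/`t2` may be `NULL`
#'   if a period is missing (the test for that period is skipped).
#' @param alpha significance cutoff (default 0.05).
#' @param n_perm permutations per test (default 10000).
#' @param seed integer seed.
#' @param subject_id optional id carried into the result.
#' @return a one-row data frame (class `stratification_result`): t and p per
#'   period (NA when skipped), `label` in `{"Responder", "NonResponder"}`,
#'   and `n_permutations`.
#' @export
stratify <- function(baseline, t1 = NULL, t2 = NULL, alpha = 0.05,
                     n_perm = 10000, seed = 1L, subject_id = NA_character_) {
  if (length(baseline) < 2L)
    stop("baseline period must contain at least 2 ratings", call. = FALSE)
  if (is.null(t1) && is.null(t2))
    stop("at least one treatment period is required", call. = FALSE)
  one <- function(tr, offs) {
    if (is.null(tr) || length(tr) < 2L)
      return(list(t = NA_real_, p = NA_real_, signif_dim = FALSE))
    res <- permutation_response_test(baseline, tr, n_perm = n_perm,
                                     seed = seed + offs)
    list(t = res$t, p = res$p,
         signif_dim = res$p < alpha && mean(tr) < mean(baseline))
  }
  r1 <- one(t1, 0L); r2 <- one(t2, 1L)
  out <- data.frame(
    subject_id = subject_id,
    t_bl_vs_t1 = r1$t, p_t1 = r1$p,
    t_bl_vs_t2 = r2$t, p_t2 = r2$p,
    label = if (r1$signif_dim || r2$signif_dim) "Responder" else "NonResponder",
    n_permutations = as.integer(n_perm),
    stringsAsFactors = FALSE)
  class(out) <- c("stratification_result", class(out))
  out
}

#' Stratify every subject of a labelled rating table
#'
#' Convenience wrapper applying [stratify()] per subject of a rating table
#' carrying `subject_id`, `vas` and `period` columns. Per-subject RNG
#' streams are derived by hashing the subject id, so subject order never
#' changes results.
#'
#' @param ratings labelled ratings (see [assign_periods()]).
#' @param alpha,n_perm,seed see [stratify()].
#' @return data frame with one row per subject.
#' @export
stratify_cohort <- function(ratings, alpha = 0.05, n_perm = 10000, seed = 1L) {
  stopifnot(all(c("subject_id", "vas", "period") %in% names(ratings)))
  ids <- sort(unique(as.character(ratings$subject_id)))
  rows <- lapply(ids, function(id) {
    x <- ratings[ratings$subject_id == id, ]
    per <- function(p) x$vas[x$period == p]
    t1 <- per("T1"); t2 <- per("T2")
    stratify(per("BL"),
             t1 = if (length(t1)) t1 else NULL,
             t2 = if (length(t2)) t2 else NULL,
             alpha = alpha, n_perm = n_perm,
             seed = derive_seed(seed, id), subject_id = id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Magnitude of response and percent analgesia
#'
#' The magnitude of response is the largest difference between the averaged
#' baseline ratings and the averaged ratings of the last week of each
#' treatment period; %analgesia expresses it relative to the baseline mean.
#'
#' @param baseline baseline-period VAS ratings (mean must be positive).
#' @param t1_last_week,t2_last_week ratings from the final 7 calendar days
#'   of each treatment period; one may be `NULL`/empty.
#' @param subject_id optional id carried into the result.
#' @return one-row data frame: `magnitude_units` (VAS units),
#'   `pct_analgesia`, `period_of_max` (`"T1"` or `"T2"`).
#' @examples
#' magnitude_of_response(rep(6, 10), rep(4, 10), rep(4.5, 10))
#' @export
magnitude_of_response <- function(baseline, t1_last_week = NULL,
                                  t2_last_week = NULL,
                                  subject_id = NA_character_) {
  if (length(baseline) == 0L)
    stop("baseline period is empty", call. = FALSE)
  bl <- mean(baseline)
  if (bl <= 0)
    stop("baseline mean must be positive to express %analgesia",
         call. = FALSE)
  diffs <- c(T1 = if (length(t1_last_week)) bl - mean(t1_last_week) else NA,
             T2 = if (length(t2_last_week)) bl - mean(t2_last_week) else NA)
  if (all(is.na(diffs)))
    stop("at least one treatment last-week window must be nonempty",
         call. = FALSE)
  k <- which.max(diffs)   # NA-safe: which.max ignores NA
  data.frame(subject_id = subject_id,
             magnitude_units = unname(diffs[k]),
             pct_analgesia = 100 * unname(diffs[k]) / bl,
             period_of_max = names(diffs)[k],
             stringsAsFactors = FALSE)
}

#' Per-subject analgesia summary from labelled ratings
#'
#' Extracts the final 7 calendar days of each treatment period (per subject,
#' using that subject's visit dates) and applies [magnitude_of_response()].
#'
#' @param ratings labelled ratings with `subject_id`, `timestamp`, `vas`,
#'   `period`.
#' @param visits data frame `subject_id`, `visit_1` ... `visit_6` (dates).
#' @return data frame with one row per subject.
#' @export
analgesia_summary <- function(ratings, visits) {
  ids <- sort(unique(as.character(ratings$subject_id)))
  rows <- lapply(ids, function(id) {
    x <- ratings[ratings$subject_id == id, ]
    v <- visits[visits$subject_id == id, ]
    if (nrow(v) != 1L)
      stop(sprintf("no visit dates for subject '%s'", id), call. = FALSE)
    lastweek <- function(period, end_visit) {
      end <- as.POSIXct(as.Date(v[[end_visit]]), tz = "UTC")
      sel <- x$period == period &
        as.POSIXct(x$timestamp, tz = "UTC") >= end - 7 * 86400
      x$vas[sel]
    }
    magnitude_of_response(x$vas[x$period == "BL"],
                          lastweek("T1", "visit_3"),
                          lastweek("T2", "visit_5"),
                          subject_id = id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect size of placebo pill ingestion
#'
#' The difference between mean analgesia in the placebo-treated arm and in
#' the no-treatment arm, divided by the standard deviation of all the data
#' (pooled concatenation, sample SD with n-1 denominator).
#'
#' @param analgesia_ptx,analgesia_notx numeric vectors of per-subject
#'   analgesia (units or percent) for the two arms.
#' @return scalar effect size.
#' @export
pill_effect_size <- function(analgesia_ptx, analgesia_notx) {
  if (length(analgesia_ptx) == 0L || length(analgesia_notx) == 0L)
    stop("both arms must be nonempty", call. = FALSE)
  s <- sd(c(analgesia_ptx, analgesia_notx))
  if (!is.finite(s) || s == 0)
    stop("pooled standard deviation is zero; effect size undefined",
         call. = FALSE)
  (mean(analgesia_ptx) - mean(analgesia_notx)) / s
}

#' Chi-squared contrast of two response rates
#'
#' Pearson chi-squared test (df = 1, no continuity correction) on the 2x2
#' table of responders/non-responders in two arms.
#'
#' @param resp_a,n_a responders and total in arm A.
#' @param resp_b,n_b responders and total in arm B.
#' @return list with `chi2`, `p`, and the 2x2 `table`.
#' @examples
#' response_rate_chi2(24, 43, 4, 20) # chi2 approx 7.09
#' @export
response_rate_chi2 <- function(resp_a, n_a, resp_b, n_b) {
  resp_a <- stopifnot_count(resp_a, "resp_a"); n_a <- stopifnot_count(n_a, "n_a", 1L)
  resp_b <- stopifnot_count(resp_b, "resp_b"); n_b <- stopifnot_count(n_b, "n_b", 1L)
  if (resp_a > n_a || resp_b > n_b)
    stop("responder count exceeds arm size", call. = FALSE)
  tab <- matrix(c(resp_a, n_a - resp_a, resp_b, n_b - resp_b), nrow = 2,
                dimnames = list(c("Responder", "NonResponder"),
                                c("A", "B")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the 2x2 table is zero; chi-squared undefined",
         call. = FALSE)
  ht <- chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value), table = tab)
}

#' Single-pass outlier mask
#'
#' Flags values further than `k` standard deviations from the mean, in a
#' single pass (mean and SD are not recomputed after exclusion). With zero
#' SD every value is included.
#'
#' @param values numeric vector (length >= 2).
#' @param k multiple of the SD (default 3).
#' @return logical inclusion mask (`FALSE` marks outliers).
#' @export
exclude_outliers <- function(values, k = 3) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("need at least 2 values", call. = FALSE)
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values, na.rm = TRUE)) <= k * s
}
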