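t0 <- as.POSIXct("2024-01-01 10:00:00", tz = "UTC")

test_that("dedupe keeps the last entry of a 30-min window and respects gaps", {
  mk <- function(mins, vas) data.frame(timestamp = t0 + mins * 60, vas = vas)

  # pair inside the window: only the later survives
  out <- dedupe_ratings(mk(c(0, 25), c(6, 5)))
  expect_equal(out$vas, 5)

  # pair outside the window: both survive
  out <- dedupe_ratings(mk(c(0, 31), c(6, 5)))
  expect_equal(out$vas, c(6, 5))

  # chained run 10:00, 10:20, 10:40 collapses to its final member
  out <- dedupe_ratings(mk(c(0, 20, 40), c(6, 5, 4)))
  expect_equal(out$vas, 4)

  # empty input passes through
  expect_equal(nrow(dedupe_ratings(mk(numeric(0), numeric(0)))), 0)
})

test_that("dedupe property: no two retained entries within 30 minutes", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      x <- data.frame(timestamp = t0 + sort(sample.int(600, n)) * 60,
                      vas = round(runif(n, 0, 10), 1))
      out <- dedupe_ratings(x)
      if (nrow(out) > 1)
        expect_true(all(diff(as.numeric(out$timestamp)) >= 30 * 60))
      # the last raw entry always survives
      expect_equal(out$timestamp[nrow(out)], x$timestamp[n])
    }
  })
})

test_that("period assignment uses half-open intervals and drops out-of-trial entries", {
  vd <- test_visits()
  x <- data.frame(timestamp = as.POSIXct(c(vd[1] - 1, vd[1], vd[2], vd[6]),
                                         tz = "UTC"),
                  vas = c(5, 5, 4, 3))
  expect_message(out <- assign_periods(x, vd), "dropped 2")
  # entry exactly at a visit boundary goes to the later period
  expect_equal(out$period, c("BL", "T1"))

  all_before <- data.frame(timestamp = as.POSIXct(vd[1], tz = "UTC") - 1:3,
                           vas = c(5, 5, 5))
  expect_message(out2 <- assign_periods(all_before, vd), "dropped 3")
  expect_equal(nrow(out2), 0)

  expect_error(assign_periods(x, vd[1]), "at least 2")
  expect_error(assign_periods(x, rev(vd)), "strictly increasing")

  # 14-day baseline at 2/day full compliance -> 28 BL entries
  full <- data.frame(
    timestamp = as.POSIXct(vd[1], tz = "UTC") +
      rep(0:13, each = 2) * 86400 + c(9, 21) * 3600,
    vas = 5)
  expect_equal(sum(assign_periods(full, vd)$period == "BL"), 28)
})

test_that("permutation p agrees with exhaustive enumeration on small samples", {
  bl <- c(7, 7, 8, 7); tr <- c(3, 3, 2, 3)
  p_exact <- exhaustive_perm_p(bl, tr)
  expect_equal(p_exact, 2 / 70)   # frozen: only the 2 extreme partitions

  res <- permutation_response_test(bl, tr, n_perm = 4000, seed = 11)
  # Monte-Carlo estimate within 4 binomial SDs of the exact value
  # (the +1 correction biases slightly upward)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p - p_exact), 4 * se + 1 / 4001)
  expect_gt(res$t, 0)   # diminution -> positive t
  expect_lt(res$p, 0.05)

  # a second, asymmetric case against the enumeration oracle
  bl2 <- c(6, 5, 7, 6, 8); tr2 <- c(5, 4, 6, 5)
  p2 <- exhaustive_perm_p(bl2, tr2)
  r2 <- permutation_response_test(bl2, tr2, n_perm = 4000, seed = 12)
  expect_lt(abs(r2$p - p2), 4 * sqrt(p2 * (1 - p2) / 4000) + 1 / 4001)
})

test_that("permutation test symmetry, determinism and degenerate input", {
  bl <- c(7, 7, 8, 7); tr <- c(3, 3, 2, 3)
  a <- permutation_response_test(bl, tr, n_perm = 500, seed = 3)
  b <- permutation_response_test(tr, bl, n_perm = 500, seed = 3)
  expect_equal(a$t, -b$t)
  # same-seed reruns are identical
  expect_identical(a, permutation_response_test(bl, tr, n_perm = 500, seed = 3))

  # identical constants: p = 1 by convention
  z <- permutation_response_test(rep(5, 4), rep(5, 4), n_perm = 200, seed = 1)
  expect_equal(z$p, 1)
  expect_equal(z$t, 0)

  expect_error(permutation_response_test(5, c(4, 4)), "at least 2")
})

test_that("stratification requires a significant diminution, not any change", {
  withr::with_seed(5, {
    bl <- rnorm(28, 6, 0.8)
    worse <- rnorm(28, 8, 0.8)    # significant *increase*
    better <- rnorm(28, 4, 0.8)
    flat <- rnorm(28, 6, 0.8)
  })
  s_worse <- stratify(bl, t1 = worse, t2 = flat, n_perm = 500, seed = 1)
  expect_equal(s_worse$label, "NonResponder")
  expect_lt(s_worse$p_t1, 0.05)   # significant, but wrong direction

  s_resp <- stratify(bl, t1 = better, t2 = flat, n_perm = 500, seed = 1)
  expect_equal(s_resp$label, "Responder")

  s_flat <- stratify(bl, t1 = flat, t2 = NULL, n_perm = 500, seed = 1)
  expect_equal(s_flat$label, "NonResponder")
  expect_true(is.na(s_flat$p_t2))   # skipped period recorded as absent
})

test_that("a planted 33% analgesia subject is stratified Responder", {
  p <- small_params(seed = 9, analgesia_pct_sd = 0, miss_prob = 0)
  vd <- test_visits()
  hits <- vapply(1:10, function(k) {
    r <- placeborct:::simulate_ratings(sprintf("S%02d", k), 6.1, 33, p, vd,
                                       seed = 1000 + k)
    r <- suppressMessages(assign_periods(r, vd))
    s <- stratify(r$vas[r$period == "BL"], r$vas[r$period == "T1"],
                  r$vas[r$period == "T2"], n_perm = 500, seed = k)
    s$label == "Responder"
  }, logical(1))
  expect_gte(mean(hits), 0.9)   # power check
})

test_that("magnitude of response and %analgesia follow their definitions", {
  m <- magnitude_of_response(rep(6, 10), rep(4, 10), rep(4.5, 10))
  expect_equal(m$magnitude_units, 2)
  expect_equal(m$pct_analgesia, 100 * 2 / 6)
  expect_equal(m$period_of_max, "T1")

  m2 <- magnitude_of_response(rep(6, 10), rep(6, 10), rep(6, 10))
  expect_equal(m2$magnitude_units, 0)
  expect_equal(m2$pct_analgesia, 0)

  m3 <- magnitude_of_response(rep(6, 10), rep(5, 10), rep(4, 10))
  expect_equal(m3$period_of_max, "T2")

  expect_error(magnitude_of_response(numeric(0), rep(4, 3)), "empty")
  # only one treatment window present
  m4 <- magnitude_of_response(rep(6, 5), t2_last_week = rep(3, 5))
  expect_equal(m4$period_of_max, "T2")
})

test_that("pill effect size matches direct formula evaluation and is scale invariant", {
  expect_equal(pill_effect_size(c(2, 2), c(1, 1)), 1 / sd(c(2, 2, 1, 1)))
  expect_equal(pill_effect_size(c(2, 2), c(1, 1)), 1.732051, tolerance = 1e-6)
  expect_equal(pill_effect_size(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- c(2, 3, 4); y <- c(1, 2, 2.5)
  expect_equal(pill_effect_size(3 * x, 3 * y), pill_effect_size(x, y))
  expect_error(pill_effect_size(c(1, 1), c(1, 1)), "zero")
})

test_that("response-rate chi-squared matches the textbook formula", {
  # 10/20 vs 5/20, expected counts by hand
  expect_equal(response_rate_chi2(10, 20, 5, 20)$chi2,
               chi2_by_hand(10, 10, 5, 15))
  expect_equal(chi2_by_hand(10, 10, 5, 15), 8 / 3)
  # equal proportions -> 0
  expect_equal(response_rate_chi2(10, 20, 5, 10)$chi2, 0)
  # zero margin -> error
  expect_error(response_rate_chi2(0, 20, 0, 20), "margin")
  expect_error(response_rate_chi2(25, 20, 5, 20), "exceeds")
})

test_that("outlier mask is a single pass at k standard deviations", {
  x <- c(rep(0, 20), 100)
  mask <- exclude_outliers(x)
  expect_equal(sum(!mask), 1)
  expect_false(mask[21])
  # verify against direct computation
  expect_equal(mask, abs(x - mean(x)) <= 3 * sd(x))

  expect_true(all(exclude_outliers(rep(4, 10))))       # zero sd
  expect_true(all(exclude_outliers(c(x, 100), k = 1e6)))  # huge k
  expect_error(exclude_outliers(5), "at least 2")
})

test_that("%analgesia is invariant to a uniform time shift of all ratings", {
  p <- small_params(seed = 21)
  vd <- test_visits()
  r <- placeborct:::simulate_ratings("S1", 6, 30, p, vd, seed = 77)
  lab1 <- suppressMessages(assign_periods(r, vd))
  shift <- r; shift$timestamp <- shift$timestamp + 3 * 86400
  lab2 <- suppressMessages(assign_periods(shift, vd + 3))
  lw <- function(lab, vd) {
    end3 <- as.POSIXct(vd[3], tz = "UTC"); end5 <- as.POSIXct(vd[5], tz = "UTC")
    magnitude_of_response(
      lab$vas[lab$period == "BL"],
      lab$vas[lab$period == "T1" & lab$timestamp >= end3 - 7 * 86400],
      lab$vas[lab$period == "T2" & lab$timestamp >= end5 - 7 * 86400])
  }
  expect_equal(lw(lab1, vd)$pct_analgesia, lw(lab2, vd + 3)$pct_analgesia)
})
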