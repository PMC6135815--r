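# Reduced hyperparameter grids keep the nested procedures quick while
# exercising the same code paths as the full defaults.
fast_grid <- list(cost_grid = 10^(-1:1), gamma_grid = 10^(-2:0))

# Planted linear cohort for regression checks.
planted_regression <- function(n = 43, p = 38, k = 6, seed = 1,
                               beta = 1, noise = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("sc%02d", 1:p)))
    y <- X[, 1:k] %*% rep(beta, k) + rnorm(n, 0, noise)
  })
  list(X = X, y = as.numeric(y), planted = sprintf("sc%02d", 1:k))
}

test_that("Clopper-Pearson intervals are exact and bracket the estimate", {
  ci <- clopper_pearson(31, 43)
  expect_equal(round(unname(ci), 2), c(0.56, 0.85))
  expect_true(ci["lower"] < 31 / 43 && 31 / 43 < ci["upper"])
  expect_equal(unname(clopper_pearson(0, 10)["lower"]), 0)
  expect_equal(unname(clopper_pearson(10, 10)["upper"]), 1)
  expect_error(clopper_pearson(5, 0), ">= 1")
  expect_error(clopper_pearson(11, 10), "successes > n")
})

test_that("exact binomial CIs achieve at least nominal coverage", {
  withr::with_seed(88, {
    p_true <- 0.6; n <- 25
    covered <- vapply(1:400, function(i) {
      x <- rbinom(1, n, p_true)
      ci <- clopper_pearson(x, n)
      ci["lower"] <= p_true && p_true <= ci["upper"]
    }, logical(1))
  })
  expect_gte(mean(covered), 0.95 - 2 * sqrt(0.95 * 0.05 / 400))
})

test_that("nested LOOCV SVM separates a linearly separable cohort", {
  withr::with_seed(90, {
    n <- 24
    y <- factor(rep(c("Responder", "NonResponder"), each = n / 2))
    X <- matrix(rnorm(n * 5), n, 5)
    X[, 1] <- X[, 1] + ifelse(y == "Responder", 3, -3)
  })
  rep <- do.call(nested_loocv_classify,
                 c(list(X = X, y = y, inner_folds = 5, seed = 7), fast_grid))
  expect_gte(rep$accuracy["estimate"], 0.9)
  expect_equal(sum(rep$confusion), n)
  expect_true(rep$accuracy["lower"] <= rep$accuracy["estimate"])
  # determinism
  rep2 <- do.call(nested_loocv_classify,
                  c(list(X = X, y = y, inner_folds = 5, seed = 7), fast_grid))
  expect_identical(rep$predictions, rep2$predictions)
})

test_that("shuffled labels land inside the null accuracy distribution", {
  withr::with_seed(91, {
    n <- 20
    y <- factor(rep(c("Responder", "NonResponder"), each = n / 2))
    X <- matrix(rnorm(n * 4), n, 4)
    X[, 1] <- X[, 1] + ifelse(y == "Responder", 3, -3)
    y_shuf <- sample(y)
  })
  obs <- do.call(nested_loocv_classify,
                 c(list(X = X, y = y, inner_folds = 5, seed = 8), fast_grid))
  nul <- do.call(accuracy_null,
                 c(list(X = X, y = y,
                        observed_accuracy = obs$accuracy["estimate"],
                        n_label_draws = 24, seed = 9, inner_folds = 5),
                   fast_grid))
  # strong planted signal clears the 1.96-sigma null threshold
  expect_gt(nul$z, 1.96)
  expect_gt(obs$accuracy["estimate"], nul$threshold)
  # an accuracy measured on shuffled labels does not
  shuf <- do.call(nested_loocv_classify,
                  c(list(X = X, y = y_shuf, inner_folds = 5, seed = 10),
                    fast_grid))
  expect_lte(shuf$accuracy["estimate"],
             max(nul$null) + 1e-9)
  z_shuf <- (shuf$accuracy["estimate"] - nul$mean_null) / nul$sd_null
  expect_lt(z_shuf, 1.96)
})

test_that("robust selection keeps true features and resists contamination", {
  withr::with_seed(92, {
    n <- 40
    y <- rnorm(n)
    X <- cbind(copy = y,                        # exact copy: must be selected
               noise = rnorm(n),
               contam = rnorm(n))
    # single gross outcome outlier at a moderately informative feature
    # value: classical least squares latches on, the bisquare fit must not
    y_c <- y; y_c[1] <- 15; X[1, "contam"] <- 5
  })
  sel <- select_features_robust(X, y_c, p_thresh = 0.001)
  expect_true("copy" %in% sel)
  expect_false("contam" %in% sel)
  # the least-squares oracle does select the contaminated feature
  p_ols <- summary(lm(y_c ~ X[, "contam"]))$coefficients[2, 4]
  expect_lt(p_ols, 0.001)
  expect_error(select_features_robust(X[1:5, ], y[1:5]), "at least 10")
})

test_that("null features pass the robust screen at about the nominal rate", {
  withr::with_seed(93, {
    n <- 60; p <- 400
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
  })
  sel <- select_features_robust(X, y, p_thresh = 0.001)
  # expected ~ 0.001 * 400 = 0.4 selections
  expect_lte(length(sel), 4)
})

test_that("nested LOOCV LASSO recovers planted subscales in consensus weights", {
  d <- planted_regression(n = 43, seed = 94)
  rep <- nested_loocv_lasso(d$X, d$y, selection = NULL, inner_folds = 10,
                            seed = 11)
  expect_gt(rep$r, 0.5)   # out-of-fold prediction tracks the outcome
  cw <- rep$consensus
  planted <- cw$feature %in% d$planted
  expect_gt(min(cw$frequency[planted]), max(0, mean(cw$frequency[!planted])))
  ratio <- stats::median(abs(cw$consensus_weight[planted])) /
    max(1e-12, stats::median(abs(cw$consensus_weight[!planted])))
  expect_gt(ratio, 5)
})

test_that("LASSO on pure noise predicts nothing; forced lambda zeroes the model", {
  withr::with_seed(95, {
    X <- matrix(rnorm(30 * 10), 30, 10)
    y <- rnorm(30)
  })
  rep <- nested_loocv_lasso(X, y, selection = NULL, inner_folds = 5, seed = 12)
  # no positive predictive skill (out-of-fold r on noise is zero-centered
  # or negatively biased, never reliably positive)
  expect_lt(rep$r, 0.3)
  # lambda -> infinity: all weights zero, constant prediction
  rep2 <- nested_loocv_lasso(X, y, selection = NULL, inner_folds = 5,
                             seed = 12, lambda = c(1e6, 1e5))
  expect_true(all(vapply(rep2$per_fold, function(w) all(w == 0), logical(1))))
  expect_lt(diff(range(rep2$predictions$predicted)), 0.5)
})

test_that("empty in-fold selection falls back to the training mean", {
  withr::with_seed(96, {
    X <- matrix(rnorm(15 * 4), 15, 4)
    y <- rnorm(15)
  })
  never <- function(X_train, y_train, ...) character(0)
  expect_message(rep <- nested_loocv_lasso(X, y, selection = never,
                                           inner_folds = 5, seed = 13),
                 "empty selection")
  expect_equal(rep$predictions$predicted[1], mean(y[-1]))
})

test_that("no leakage: corrupting a held-out outcome never changes its prediction", {
  # classification
  withr::with_seed(97, {
    n <- 16
    y <- factor(rep(c("Responder", "NonResponder"), n / 2))
    X <- matrix(rnorm(n * 3), n, 3)
    X[, 1] <- X[, 1] + ifelse(y == "Responder", 2, -2)
  })
  base <- do.call(nested_loocv_classify,
                  c(list(X = X, y = y, inner_folds = 5, seed = 14), fast_grid))
  for (i in c(1L, 7L)) {
    y_c <- y
    y_c[i] <- setdiff(levels(y), as.character(y[i]))   # corrupt subject i
    alt <- do.call(nested_loocv_classify,
                   c(list(X = X, y = y_c, inner_folds = 5, seed = 14),
                     fast_grid))
    expect_identical(alt$predictions$predicted[i],
                     base$predictions$predicted[i])
  }
  # regression
  d <- planted_regression(n = 16, p = 6, k = 2, seed = 98)
  rbase <- nested_loocv_lasso(d$X, d$y, selection = NULL, inner_folds = 5,
                              seed = 15)
  y_c <- d$y; y_c[3] <- 1e3
  ralt <- nested_loocv_lasso(d$X, y_c, selection = NULL, inner_folds = 5,
                             seed = 15)
  expect_equal(ralt$predictions$predicted[3], rbase$predictions$predicted[3])
})

test_that("consensus weight bookkeeping follows the averaging rule", {
  w <- c(a = 2, b = -1)
  folds <- list(w, w, c(a = 2), c(a = 2, b = -1))
  cw <- consensus_weights(folds, report_threshold = 0.84)
  expect_equal(cw$consensus_weight[cw$feature == "a"], 2)
  expect_equal(cw$frequency[cw$feature == "a"], 1)
  expect_true(cw$flag[cw$feature == "a"])
  # b selected in 3 of 4 folds: mean includes the absent-as-zero fold
  expect_equal(cw$consensus_weight[cw$feature == "b"], -3 / 4)
  expect_equal(cw$frequency[cw$feature == "b"], 0.75)
  expect_false(cw$flag[cw$feature == "b"])
  # 43 folds at threshold 0.84: the flag requires selection in >= 37 folds
  f36 <- consensus_weights(c(rep(list(c(x = 1)), 36), rep(list(NULL), 7)))
  f37 <- consensus_weights(c(rep(list(c(x = 1)), 37), rep(list(NULL), 6)))
  expect_false(f36$flag)
  expect_true(f37$flag)
  # never-selected features appear with zero weight when a universe is given
  cw2 <- consensus_weights(folds, all_features = c("a", "b", "c"))
  expect_equal(cw2$consensus_weight[cw2$feature == "c"], 0)
  expect_equal(cw2$frequency[cw2$feature == "c"], 0)
})

test_that("model comparison separates independent from redundant predictors", {
  withr::with_seed(99, {
    n <- 200
    pa <- rnorm(n); pb <- rnorm(n)          # orthogonal predictors
    actual <- pa + pb + rnorm(n, 0, 0.5)
    noise <- rnorm(n)
  })
  cmp <- compare_predictions(pa, pb, actual)
  expect_lt(abs(cmp$r_ab), 0.15)
  r2a <- summary(lm(actual ~ pa))$r.squared
  r2b <- summary(lm(actual ~ pb))$r.squared
  expect_lt(abs(cmp$r_squared - (r2a + r2b)), 0.1)
  expect_false(cmp$collinear)
  # pure-noise second predictor: its partial coefficient is ~0
  cmp2 <- compare_predictions(pa, noise, actual)
  expect_lt(abs(cmp2$joint["pred_b", "Estimate"]), 0.2)
  expect_gt(cmp2$joint["pred_b", "Pr(>|t|)"], 0.01)
  # identical predictions are flagged collinear
  expect_warning(cmp3 <- compare_predictions(pa, pa, actual), "collinear")
  expect_true(cmp3$collinear)
  expect_equal(cmp3$r_ab, 1)
})

test_that("correlation difference z-test matches the Fisher formula", {
  eq <- correlation_difference_z(0.5, 30, 0.5, 40)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # frozen hand evaluation: atanh(.6)/sqrt(1/40 + 1/16)
  hand <- correlation_difference_z(0.6, 43, 0.0, 19)
  expect_equal(hand$z, 2.343265, tolerance = 1e-6)
  expect_equal(hand$p, 0.0191158, tolerance = 1e-5)
  # antisymmetry
  expect_equal(correlation_difference_z(0.0, 19, 0.6, 43)$z, -hand$z)
  expect_error(correlation_difference_z(0.5, 3, 0.5, 40), "exceed 3")
  expect_error(correlation_difference_z(1, 30, 0.5, 40), "strictly inside")
})
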