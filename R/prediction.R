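# Cross-validated prediction of placebo response: nested leave-one-out SVM
# classification and LASSO regression with in-fold feature selection,
# permutation-null calibration, exact binomial CIs, consensus weight maps,
# and cross-model comparison.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param successes,n counts, `0 <= successes <= n`, `n >= 1`.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @examples
#' clopper_pearson(31, 43) # approx (0.56, 0.85)
#' @export
clopper_pearson <- function(successes, n, conf = 0.95) {
  successes <- stopifnot_count(successes, "successes")
  n <- stopifnot_count(n, "n", min = 1L)
  if (successes > n) stop("successes > n", call. = FALSE)
  a <- 1 - conf
  lower <- if (successes == 0) 0 else qbeta(a / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - a / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

# Stratified fold assignment: by class for factors, by outcome quantile for
# numeric outcomes. Deterministic given the RNG state.
stratified_folds <- function(y, k) {
  n <- length(y)
  folds <- integer(n)
  if (is.numeric(y)) {
    strata <- cut(rank(y, ties.method = "first"),
                  breaks = max(1L, min(k, floor(n / k))), labels = FALSE)
  } else {
    strata <- as.integer(factor(y))
  }
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Nested leave-one-out SVM classification
#'
#' Outer loop: each subject in turn is held out and predicted by a model
#' fit on the remaining `n - 1`. Inner loop: the RBF-kernel SVM's box
#' constraint (cost) and kernel scale (gamma) are tuned by stratified
#' k-fold cross-validation *within the training fold*, taking the grid
#' point with the least inner misclassification error (first in grid order
#' on ties). Features are z-scored with training-fold statistics only.
#'
#' @param X subjects x features matrix (no missing values).
#' @param y two-level factor (or coercible) of class labels.
#' @param cost_grid,gamma_grid hyperparameter grids (default
#'   `10^(-3:3)` each).
#' @param inner_folds inner folds (default 10).
#' @param seed integer seed.
#' @param positive label treated as "positive" for sensitivity (defaults to
#'   `"Responder"` when present, else the first level).
#' @return list of class `classifier_report`: `predictions` (data frame
#'   subject, actual, predicted), `accuracy`, `sensitivity`, `specificity`
#'   each with exact 95% CI, `confusion`, `tuned` (per-fold cost/gamma).
#' @export
nested_loocv_classify <- function(X, y, cost_grid = 10^(-3:3),
                                  gamma_grid = 10^(-3:3), inner_folds = 10,
                                  seed = 1L, positive = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (nlevels(y) != 2L) stop("y must have exactly two classes", call. = FALSE)
  if (n < inner_folds + 1L)
    stop("need at least inner_folds + 1 subjects", call. = FALSE)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  if (is.null(positive))
    positive <- if ("Responder" %in% levels(y)) "Responder" else levels(y)[1]

  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  pred <- character(n)
  tuned <- data.frame(subject = seq_len(n), cost = NA_real_, gamma = NA_real_)

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2L)
      stop("a training fold is missing a class", call. = FALSE)
    nz <- normalize_features(X[tr, , drop = FALSE], X[i, , drop = FALSE])
    folds <- with_seed(derive_seed(seed, paste0("fold", i)),
                       stratified_folds(ytr, inner_folds))
    err <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(inner_folds), function(f) {
        itr <- folds != f
        if (length(unique(ytr[itr])) < 2L || !any(!itr)) return(NA_real_)
        fit <- e1071::svm(nz$train[itr, , drop = FALSE], ytr[itr],
                          kernel = "radial", cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = FALSE)
        mean(predict(fit, nz$train[!itr, , drop = FALSE]) != ytr[!itr])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    best <- which.min(err)   # first grid point on ties
    tuned$cost[i] <- grid$cost[best]; tuned$gamma[i] <- grid$gamma[best]
    fit <- e1071::svm(nz$train, ytr, kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE)
    pred[i] <- as.character(predict(fit, nz$test))
  }

  actual <- as.character(y)
  tp <- sum(pred == positive & actual == positive)
  tn <- sum(pred != positive & actual != positive)
  fp <- sum(pred == positive & actual != positive)
  fn <- sum(pred != positive & actual == positive)
  metric <- function(x, m) c(estimate = if (m > 0) x / m else NA_real_,
                             if (m > 0) clopper_pearson(x, m)
                             else c(lower = NA_real_, upper = NA_real_))
  structure(list(
    predictions = data.frame(subject = seq_len(n), actual = actual,
                             predicted = pred, stringsAsFactors = FALSE),
    confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
    accuracy = metric(tp + tn, n),
    sensitivity = metric(tp, tp + fn),
    specificity = metric(tn, tn + fp),
    positive = positive, tuned = tuned, seed = seed),
    class = "classifier_report")
}

#' Null accuracy distribution from scrambled labels
#'
#' Repeats the full nested cross-validated classification on randomly
#' permuted labels to obtain the null accuracy distribution, and expresses
#' the observed accuracy as a z score against it. The significance
#' threshold is `mean(null) + 1.96 * sd(null)`.
#'
#' @param X,y as in [nested_loocv_classify()].
#' @param observed_accuracy observed accuracy to calibrate (e.g. from
#'   [nested_loocv_classify()]).
#' @param n_label_draws number of label permutations (default 1000).
#' @param seed integer seed.
#' @param ... further arguments (grids, folds) passed on.
#' @return list: `null` (accuracies), `z`, `threshold`, `mean_null`,
#'   `sd_null`.
#' @export
accuracy_null <- function(X, y, observed_accuracy, n_label_draws = 1000,
                          seed = 1L, ...) {
  n_label_draws <- stopifnot_count(n_label_draws, "n_label_draws", 2L)
  y <- factor(y)
  null <- vapply(seq_len(n_label_draws), function(b) {
    yb <- with_seed(derive_seed(seed, paste0("draw", b)), sample(y))
    rep <- nested_loocv_classify(X, yb, seed = derive_seed(seed, paste0("cv", b)),
                                 ...)
    unname(rep$accuracy["estimate"])
  }, numeric(1))
  s <- sd(null)
  if (!is.finite(s) || s == 0)
    stop("null accuracy distribution has zero spread", call. = FALSE)
  list(null = null, mean_null = mean(null), sd_null = s,
       z = (observed_accuracy - mean(null)) / s,
       threshold = mean(null) + 1.96 * s)
}

#' Robust-regression univariate feature selection
#'
#' For each feature, a robust simple regression (iteratively reweighted
#' least squares with Tukey bisquare weights, tuning constant 4.685) of the
#' continuous outcome on the feature; features whose slope attains
#' `p < p_thresh` (large-sample t test of the robust slope) are kept.
#' Zero-variance features are skipped.
#'
#' @param X_train training subjects x features matrix.
#' @param y_train continuous outcome (training subjects only).
#' @param p_thresh selection threshold (default 0.001).
#' @return character vector of selected feature names (column names of
#'   `X_train`; indices if unnamed).
#' @export
select_features_robust <- function(X_train, y_train, p_thresh = 0.001) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 10L)
    stop("need at least 10 training subjects", call. = FALSE)
  nms <- colnames(X_train)
  if (is.null(nms)) nms <- as.character(seq_len(ncol(X_train)))
  keep <- vapply(seq_len(ncol(X_train)), function(j) {
    x <- X_train[, j]
    if (sd(x) == 0) return(FALSE)
    p <- tryCatch({
      fit <- MASS::rlm(y_train ~ x, psi = MASS::psi.bisquare, c = 4.685,
                       maxit = 50)
      tv <- summary(fit)$coefficients["x", "t value"]
      2 * pt(-abs(tv), df = length(y_train) - 2)
    }, error = function(e) NA_real_)
    isTRUE(p < p_thresh)
  }, logical(1))
  nms[keep]
}

#' Nested leave-one-out LASSO regression
#'
#' Outer loop: each subject is held out in turn. Within each training fold,
#' features are selected by `selection` (training subjects only), the LASSO
#' penalty `lambda` is tuned by stratified (outcome-quantile) inner k-fold
#' cross-validation taking the least mean squared error, the model is
#' refit, and the held-out subject is predicted. Features are z-scored
#' with training-fold statistics only. A fold with an empty selection
#' predicts the training-fold outcome mean (logged via a message).
#'
#' @param X subjects x named features matrix.
#' @param y continuous outcome (e.g. %analgesia).
#' @param selection feature selection function `(X_train, y_train) ->
#'   feature names`; use `NULL` to keep all features.
#' @param inner_folds inner folds (default 10).
#' @param seed integer seed.
#' @param lambda optional fixed lambda sequence overriding the data-driven
#'   path (a single large value forces the all-zero model).
#' @param report_threshold selection-frequency threshold forwarded to
#'   [consensus_weights()].
#' @return list of class `regression_report`: `predictions` (data frame
#'   subject, actual, predicted), `r` (out-of-fold Pearson correlation),
#'   `per_fold` (list of named weight vectors), `consensus` (see
#'   [consensus_weights()]), `lambda` (per fold).
#' @export
nested_loocv_lasso <- function(X, y, selection = select_features_robust,
                               inner_folds = 10, seed = 1L, lambda = NULL,
                               report_threshold = 0.84) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < inner_folds + 1L)
    stop("need at least inner_folds + 1 subjects", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  y <- as.numeric(y)

  pred <- numeric(n)
  per_fold <- vector("list", n)
  lam <- numeric(n)
  n_empty <- 0L

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel <- if (is.null(selection)) colnames(X)
           else selection(X[tr, , drop = FALSE], y[tr])
    if (length(sel) == 0L) {
      n_empty <- n_empty + 1L
      pred[i] <- mean(y[tr])
      per_fold[[i]] <- setNames(numeric(0), character(0))
      lam[i] <- NA_real_
      next
    }
    nz <- normalize_features(X[tr, sel, drop = FALSE],
                             X[i, sel, drop = FALSE])
    if (length(sel) == 1L) {   # glmnet needs >= 2 columns; pad a null one
      xtr <- cbind(nz$train, .null. = 0)
      xte <- cbind(nz$test, .null. = 0)
    } else {
      xtr <- nz$train; xte <- nz$test
    }
    folds <- with_seed(derive_seed(seed, paste0("fold", i)),
                       stratified_folds(y[tr], inner_folds))
    cv <- glmnet::cv.glmnet(xtr, y[tr], alpha = 1, foldid = folds,
                            lambda = lambda, nlambda = 100,
                            type.measure = "mse")
    lam[i] <- cv$lambda.min
    w <- as.numeric(coef(cv, s = "lambda.min"))[-1]   # drop intercept
    names(w) <- colnames(xtr)
    w <- w[names(w) != ".null."]
    per_fold[[i]] <- w
    pred[i] <- as.numeric(predict(cv, newx = xte, s = "lambda.min"))
  }
  if (n_empty > 0L)
    message(sprintf("nested_loocv_lasso: %d fold(s) had an empty selection; predicted the training mean",
                    n_empty))

  structure(list(
    predictions = data.frame(subject = seq_len(n), actual = y,
                             predicted = pred),
    r = if (sd(pred) > 0) cor(pred, y) else NA_real_,
    per_fold = per_fold,
    consensus = consensus_weights(per_fold,
                                  report_threshold = report_threshold,
                                  all_features = colnames(X)),
    lambda = lam, n_empty_selections = n_empty, seed = seed),
    class = "regression_report")
}

#' Consensus weights across cross-validation folds
#'
#' Because the selected features and fitted weights differ between folds, a
#' single consensus set is formed by averaging each feature's weight across
#' *all* folds (weight 0 where the feature was not selected), together with
#' its selection frequency (the fraction of folds in which the feature
#' entered the model with a nonzero weight). Features selected in more than
#' `report_threshold` of folds are flagged for reporting.
#'
#' @param per_fold_weights list (one element per fold) of named numeric
#'   weight vectors over that fold's selected features.
#' @param report_threshold frequency threshold for the report flag
#'   (default 0.84, strict inequality).
#' @param all_features optional full feature universe; never-selected
#'   features then appear with weight 0 and frequency 0.
#' @return data frame: `feature`, `consensus_weight`, `frequency`, `flag`.
#' @export
consensus_weights <- function(per_fold_weights, report_threshold = 0.84,
                              all_features = NULL) {
  stopifnot(is.list(per_fold_weights), length(per_fold_weights) >= 1L)
  n_folds <- length(per_fold_weights)
  feats <- unique(c(all_features,
                    unlist(lapply(per_fold_weights, names))))
  if (length(feats) == 0L)
    return(data.frame(feature = character(0), consensus_weight = numeric(0),
                      frequency = numeric(0), flag = logical(0)))
  wsum <- setNames(numeric(length(feats)), feats)
  count <- setNames(numeric(length(feats)), feats)
  for (w in per_fold_weights) {
    if (length(w) == 0L) next
    wsum[names(w)] <- wsum[names(w)] + w
    nz <- names(w)[w != 0]          # selected = carries a nonzero weight
    count[nz] <- count[nz] + 1
  }
  out <- data.frame(feature = feats,
                    consensus_weight = unname(wsum) / n_folds,
                    frequency = unname(count) / n_folds,
                    stringsAsFactors = FALSE)
  out$flag <- out$frequency > report_threshold
  out[order(-abs(out$consensus_weight)), , drop = FALSE]
}

#' Compare two prediction vectors against the actual outcome
#'
#' Reports the Pearson correlation between the two predictions and a joint
#' two-predictor linear regression of the actual outcome on both, with each
#' predictor's partial coefficient and the joint R squared -- the check
#' that two models explain independent variance.
#'
#' @param pred_a,pred_b per-subject predictions from two models.
#' @param actual actual outcomes (same subjects, same order).
#' @return list: `r_ab` and its p, `joint` (lm summary coefficients),
#'   `r_squared`, `collinear` flag.
#' @export
compare_predictions <- function(pred_a, pred_b, actual) {
  stopifnot(length(pred_a) == length(actual),
            length(pred_b) == length(actual))
  const_a <- sd(pred_a) == 0; const_b <- sd(pred_b) == 0
  collinear <- FALSE
  r_ab <- NA_real_; p_ab <- NA_real_
  if (!const_a && !const_b) {
    ct <- cor.test(pred_a, pred_b)
    r_ab <- unname(ct$estimate); p_ab <- ct$p.value
    collinear <- abs(r_ab) > 0.999
  } else collinear <- TRUE
  fit <- lm(actual ~ pred_a + pred_b)
  sm <- summary(fit)
  if (collinear)
    warning("prediction vectors are constant or collinear; partial terms are not interpretable")
  list(r_ab = r_ab, p_ab = p_ab,
       joint = coef(sm), r_squared = sm$r.squared,
       collinear = collinear)
}

#' Fisher r-to-z test for the difference of two correlations
#'
#' Compares two independent correlation coefficients via
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p value -- e.g. predicted-vs-actual correlation in the
#' placebo arm against the no-treatment arm.
#'
#' @param r1,n1 correlation and sample size of group 1.
#' @param r2,n2 correlation and sample size of group 2.
#' @return list with `z` and `p`.
#' @export
correlation_difference_z <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("each n must exceed 3", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}
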