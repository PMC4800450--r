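#' Balanced k-fold assignment
#'
#' Randomly partitions subjects into `k` near-equal folds, redrawing until a
#' k-sample Kruskal-Wallis test finds no significant distributional
#' difference across folds for either variable (both p-values above
#' `balance_alpha`), so that training and test folds are exchangeable in
#' distribution.
#'
#' @param x,y the two variables whose fold-wise distributions must balance
#'   (predictor and response).
#' @param k number of folds.
#' @param balance_alpha acceptance threshold: both Kruskal-Wallis p-values
#'   must exceed it.
#' @param max_restarts maximum number of random partitions tried; exhausting
#'   them is an error reporting the best attempt's p-values.
#' @param seed integer seed; the partition is deterministic given it.
#' @return object of class `fold_assignment`: `fold` (index per subject in
#'   1..k), `k`, `balance_p` (named: x, y), `balance_test`
#'   ("kruskal-wallis"), `attempts`, `seed`.
#' @export
balanced_folds <- function(x, y, k = 4, balance_alpha = 0.05,
                           max_restarts = 1000, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2 * k) stop("need at least 2k subjects (n = ", n, ", k = ", k, ")")
  set.seed(as.integer(seed))
  base <- rep_len(seq_len(k), n)
  best_p <- c(x = -1, y = -1)
  for (attempt in seq_len(max_restarts)) {
    fold <- sample(base)
    px <- kruskal.test(x, factor(fold))$p.value
    py <- kruskal.test(y, factor(fold))$p.value
    if (min(px, py) > min(best_p)) best_p <- c(x = px, y = py)
    if (px > balance_alpha && py > balance_alpha) {
      return(structure(list(fold = fold, k = as.integer(k),
                            balance_p = c(x = px, y = py),
                            balance_test = "kruskal-wallis",
                            balance_alpha = balance_alpha,
                            attempts = attempt, seed = as.integer(seed)),
                       class = "fold_assignment"))
    }
  }
  stop("no balanced partition found in ", max_restarts,
       " restarts; best attempt had p(x) = ", signif(best_p["x"], 3),
       ", p(y) = ", signif(best_p["y"], 3))
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("Balanced ", x$k, "-fold assignment (n = ", length(x$fold),
      "): Kruskal-Wallis p(x) = ", signif(x$balance_p["x"], 3),
      ", p(y) = ", signif(x$balance_p["y"], 3),
      " after ", x$attempts, " attempt(s)\n", sep = "")
  invisible(x)
}

# out-of-fold predictions from per-fold simple linear regression; errors on
# constant training x
.cv_predictions <- function(x, y, fold, k) {
  pred <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    xt <- x[tr]; yt <- y[tr]
    vx <- var(xt)
    if (vx == 0) stop("constant predictor within the training set of fold ", f)
    slope <- cov(xt, yt) / vx
    intercept <- mean(yt) - slope * mean(xt)
    pred[!tr] <- intercept + slope * x[!tr]
  }
  pred
}

#' Cross-validated prediction of behavior from a neural measure
#'
#' For each fold, a simple linear regression of `y` on `x` is estimated on
#' the other folds and used to predict the held-out fold; the overall
#' predictability is `r(prediction, observation)`, the Pearson correlation
#' between the concatenated out-of-fold predictions and the observed `y`.
#' No subject's prediction ever involves a model fitted on that subject's
#' fold.
#'
#' @param x predictor (neural measure) per subject.
#' @param y response (behavioral score) per subject.
#' @param folds a [balanced_folds()] assignment covering every subject
#'   exactly once.
#' @return object of class `cv_pred`: `predicted` (per subject),
#'   `r_prediction_observation`, `folds`, `n`. Use [permutation_p()] for
#'   significance.
#' @export
cv_predict <- function(x, y, folds) {
  stopifnot(inherits(folds, "fold_assignment"))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || length(folds$fold) != n)
    stop("x, y and folds must cover the same subjects")
  if (!setequal(unique(folds$fold), seq_len(folds$k)))
    stop("fold assignment must use every fold index 1..k")
  pred <- .cv_predictions(x, y, folds$fold, folds$k)
  structure(list(predicted = pred,
                 r_prediction_observation = cor(pred, y),
                 folds = folds, n = n, observed = y),
            class = "cv_pred")
}

#' @export
print.cv_pred <- function(x, digits = 3, ...) {
  cat("Balanced ", x$folds$k, "-fold cross-validated prediction (n = ", x$n,
      "): r(prediction, observation) = ",
      signif(x$r_prediction_observation, digits), "\n", sep = "")
  if (!is.null(x$p_permutation)) {
    cat("Permutation p = ", signif(x$p_permutation, 3), " (B = ", x$B, ")\n",
        sep = "")
  }
  invisible(x)
}

#' @export
plot.cv_pred <- function(x, ...) {
  plot(x$predicted, x$observed,
       xlab = "cross-validated prediction", ylab = "observed score",
       main = sprintf("r(prediction, observation) = %.3f",
                      x$r_prediction_observation), ...)
  abline(lm(x$observed ~ x$predicted), lty = 2)
  invisible(x)
}

#' Permutation significance for cross-validated predictability
#'
#' Shuffles the predictor `B` times; each shuffle reruns the full
#' leave-fold-out prediction with the same fold assignment and records its
#' `r(prediction, observation)`, building the null distribution. The
#' p-value is one minus the percentile of the true statistic among the null
#' values, computed literally as `(number of null r >= observed r) / B`
#' (so it can be exactly 0); `smoothed = TRUE` uses the
#' `(count + 1) / (B + 1)` estimator, which cannot be 0 and is the better
#' calibrated choice.
#'
#' @param x,y,folds as in [cv_predict()].
#' @param B number of shuffles (>= 100).
#' @param seed integer seed for the shuffles.
#' @param smoothed use the (count + 1) / (B + 1) estimator.
#' @param rebalance draw a fresh balanced fold assignment for every shuffle
#'   instead of holding the observed folds fixed (the default follows the
#'   shuffle-only scheme).
#' @return the p-value, with attributes `r_observed`, `B`, `null` (the null
#'   statistics) and `smoothed`.
#' @export
permutation_p <- function(x, y, folds, B = 5000, seed = 1L, smoothed = FALSE,
                          rebalance = FALSE) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (B < 100) stop("B must be at least 100 (percentile too unstable below)")
  x <- as.numeric(x); y <- as.numeric(y)
  r_obs <- cor(.cv_predictions(x, y, folds$fold, folds$k), y)
  set.seed(as.integer(seed))
  null_r <- numeric(B)
  for (b in seq_len(B)) {
    xs <- sample(x)
    fold_b <- if (rebalance) {
      balanced_folds(xs, y, k = folds$k, balance_alpha = folds$balance_alpha,
                     seed = as.integer(seed) + b)$fold
    } else {
      folds$fold
    }
    null_r[b] <- cor(.cv_predictions(xs, y, fold_b, folds$k), y)
  }
  count <- sum(null_r >= r_obs)

  p <- if (smoothed) (count + 1) / (B + 1) else count / B
  structure(p, r_observed = r_obs, B = as.integer(B), null = null_r,
            smoothed = smoothed)
}

#' Full cross-validated predictability analysis for one variable pair
#'
#' Convenience wrapper chaining [balanced_folds()], [cv_predict()] and
#' [permutation_p()].
#'
#' @param x,y predictor and response.
#' @param k folds; `B` shuffles; `balance_alpha`, `max_restarts` as in
#'   [balanced_folds()].
#' @param B number of permutation shuffles.
#' @param balance_alpha fold-balance acceptance threshold.
#' @param max_restarts fold-balance restart budget.
#' @param seed integer seed (drives both fold assignment and shuffles).
#' @param smoothed smoothed permutation p estimator.
#' @return a `cv_pred` object with `p_permutation` and `B` filled in.
#' @export
cv_predictability <- function(x, y, k = 4, B = 5000, balance_alpha = 0.05,
                              max_restarts = 1000, seed = 1L, smoothed = FALSE) {
  folds <- balanced_folds(x, y, k = k, balance_alpha = balance_alpha,
                          max_restarts = max_restarts, seed = seed)
  res <- cv_predict(x, y, folds)
  p <- permutation_p(x, y, folds, B = B, seed = seed + 1L, smoothed = smoothed)
  res$p_permutation <- as.numeric(p)
  res$B <- attr(p, "B")
  res$seed <- as.integer(seed)
  res
}
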