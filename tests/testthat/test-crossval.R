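test_that("fold sizes are near-equal and balance p-values recorded above threshold", {
  set.seed(1)
  f8 <- balanced_folds(rnorm(8), rnorm(8), k = 4, seed = 3)
  expect_equal(as.integer(sort(table(f8$fold))), c(2L, 2L, 2L, 2L))

  f <- balanced_folds(rnorm(160), rnorm(160), k = 4, seed = 5)
  expect_true(all(f$balance_p > 0.05))
  expect_true(max(table(f$fold)) - min(table(f$fold)) <= 1)
  expect_identical(balanced_folds(rnorm(10), rnorm(10), k = 4, seed = 9)$fold,
                   balanced_folds(rnorm(10), rnorm(10), k = 4, seed = 9)$fold)
  expect_error(balanced_folds(rnorm(7), rnorm(7), k = 4), "at least 2k")
})

test_that("an adversarially ordered response is balanced where contiguous blocks fail", {
  x <- rnorm(160)
  y <- as.numeric(1:160)             # strong order structure
  f <- balanced_folds(x, y, k = 4, seed = 11)
  fold_means <- tapply(y, f$fold, mean)
  expect_lt(max(fold_means) - min(fold_means), sd(y))
  # contiguous-block folds fail the same balance test decisively
  contiguous <- rep(1:4, each = 40)
  expect_lt(kruskal.test(y, factor(contiguous))$p.value, 1e-10)
})

test_that("a noiseless linear relation is predicted perfectly out of fold", {
  x <- rnorm(20)
  y <- 2 * x
  f <- balanced_folds(x, y, k = 4, seed = 2)
  res <- cv_predict(x, y, f)
  expect_equal(res$r_prediction_observation, 1, tolerance = 1e-12)
  expect_equal(res$predicted, y, tolerance = 1e-10)
})

test_that("cv_predict equals an explicit lm-based leave-fold-out loop oracle", {
  set.seed(33)
  x <- rnorm(12)
  y <- 0.8 * x + rnorm(12)
  f <- balanced_folds(x, y, k = 4, seed = 7)
  res <- cv_predict(x, y, f)
  pred_oracle <- numeric(12)
  for (k in 1:4) {
    fit <- lm(y ~ x, data = data.frame(x = x, y = y)[f$fold != k, ])
    pred_oracle[f$fold == k] <-
      predict(fit, newdata = data.frame(x = x[f$fold == k]))
  }
  expect_equal(res$predicted, pred_oracle, tolerance = 1e-10)
  expect_equal(res$r_prediction_observation, cor(pred_oracle, y),
               tolerance = 1e-12)
})

test_that("independent variables give no spurious predictability", {
  # under the null, r(prediction, observation) carries a small NEGATIVE bias
  # (the held-out fold's responses are anti-correlated with the training
  # mean used as intercept); the estimator must never be anti-conservative
  set.seed(60)
  r <- replicate(500, {
    x <- rnorm(160); y <- rnorm(160)
    f <- balanced_folds(x, y, k = 4, seed = sample.int(1e6, 1))
    cv_predict(x, y, f)$r_prediction_observation
  })
  expect_lt(mean(r), 0.01)     # no positive bias
  expect_gt(mean(r), -0.15)    # bias is mild (about -0.08 at n = 160, k = 4)
})

test_that("no data leakage: a held-out subject's response never shapes its prediction", {
  set.seed(8)
  x <- rnorm(24)
  y <- 0.5 * x + rnorm(24)
  f <- balanced_folds(x, y, k = 4, seed = 4)
  res <- cv_predict(x, y, f)
  i <- which(f$fold == 2)[1]
  y2 <- y
  y2[i] <- y2[i] + 100                 # perturb only a held-out response
  res2 <- cv_predict(x, y2, f)
  expect_equal(res2$predicted[i], res$predicted[i], tolerance = 1e-12)
  # predictions of the other folds' members do change (y entered training)
  expect_false(isTRUE(all.equal(res2$predicted[f$fold != 2],
                                res$predicted[f$fold != 2])))
})

test_that("constant predictor in a training fold is an error", {
  x <- c(rep(1, 18), 2, 3)
  y <- rnorm(20)
  f <- structure(list(fold = rep(1:4, each = 5), k = 4L,
                      balance_p = c(x = 1, y = 1),
                      balance_test = "kruskal-wallis", balance_alpha = 0.05,
                      attempts = 1L, seed = 1L),
                 class = "fold_assignment")
  expect_error(cv_predict(x, y, f), "constant predictor")
})

test_that("permutation p has the paper-literal and smoothed extreme-rank behavior", {
  set.seed(10)
  x <- rnorm(40)
  y <- 2 * x + rnorm(40, 0, 0.05)      # true statistic beats every null draw
  f <- balanced_folds(x, y, k = 4, seed = 6)
  p_lit <- permutation_p(x, y, f, B = 200, seed = 1)
  p_sm <- permutation_p(x, y, f, B = 200, seed = 1, smoothed = TRUE)
  expect_equal(as.numeric(p_lit), 0)
  expect_equal(as.numeric(p_sm), 1 / 201)
  expect_error(permutation_p(x, y, f, B = 50), "at least 100")
})

test_that("permutation p equals a manual shuffle-and-rank oracle", {
  set.seed(14)
  x <- rnorm(16)
  y <- 0.6 * x + rnorm(16)
  f <- balanced_folds(x, y, k = 4, seed = 3)
  B <- 120
  p <- permutation_p(x, y, f, B = B, seed = 5)

  # oracle: same RNG stream, explicit lm-based CV per shuffle, manual count
  cvr <- function(xx) {
    pred <- numeric(16)
    for (k in 1:4) {
      dat <- data.frame(x = xx, y = y)
      fit <- lm(y ~ x, data = dat[f$fold != k, ])
      pred[f$fold == k] <- predict(fit, newdata = dat[f$fold == k, ])
    }
    cor(pred, y)
  }
  r_obs <- cvr(x)
  set.seed(5)
  null_r <- replicate(B, cvr(sample(x)))
  expect_equal(as.numeric(p), sum(null_r >= r_obs) / B, tolerance = 1e-12)
  expect_equal(attr(p, "null"), null_r, tolerance = 1e-10)
})

test_that("per-shuffle fold re-balancing is deterministic and agrees at decisive effects", {
  set.seed(26)
  x <- rnorm(40)
  y <- 2 * x + rnorm(40, 0, 0.05)
  f <- balanced_folds(x, y, k = 4, seed = 6)
  p1 <- permutation_p(x, y, f, B = 100, seed = 2, rebalance = TRUE)
  p2 <- permutation_p(x, y, f, B = 100, seed = 2, rebalance = TRUE)
  expect_identical(as.numeric(p1), as.numeric(p2))
  # a decisive effect beats every null draw under either scheme
  expect_equal(as.numeric(p1), 0)
  expect_equal(as.numeric(permutation_p(x, y, f, B = 100, seed = 2)), 0)
})

test_that("the observed statistic is invariant to a common subject reordering", {
  set.seed(18)
  x <- rnorm(32)
  y <- 1.5 * x + rnorm(32, 0, 0.1)
  f <- balanced_folds(x, y, k = 4, seed = 2)
  res <- cv_predict(x, y, f)
  perm <- sample(32)
  f2 <- f
  f2$fold <- f$fold[perm]
  res2 <- cv_predict(x[perm], y[perm], f2)
  expect_equal(res2$r_prediction_observation, res$r_prediction_observation,
               tolerance = 1e-12)
  expect_equal(res2$predicted, res$predicted[perm], tolerance = 1e-12)
  # with a decisive effect the permutation p agrees exactly as well
  expect_equal(as.numeric(permutation_p(x[perm], y[perm], f2, B = 100, seed = 9)),
               as.numeric(permutation_p(x, y, f, B = 100, seed = 9)))
})

test_that("planted effects survive cross-validation with shrinkage and power", {
  # cohorts at the default planted conditions: cross-validated r shrinks
  # relative to in-sample r, and the permutation test detects the effect in
  # the large majority of cohorts
  n_rep <- 60
  res <- t(vapply(seq_len(n_rep), function(s) {
    co <- generate_cohort(sim_config(seed = 4000 + s))
    d <- vapply(co$patterns, between_category_dissimilarity, numeric(1))
    y <- co$subjects$face_acc
    f <- balanced_folds(d, y, k = 4, seed = s)
    cvr <- cv_predict(d, y, f)$r_prediction_observation
    p <- as.numeric(permutation_p(d, y, f, B = 300, seed = s + 1))
    c(r_cv = cvr, r_in = cor(d, y), p = p)
  }, numeric(3)))
  expect_lt(median(res[, "r_cv"]), median(res[, "r_in"]))  # shrinkage
  expect_gt(mean(res[, "p"] < 0.05), 0.8)
})
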