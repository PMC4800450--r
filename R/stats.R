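#' Pearson correlation with its t-based p-value
#'
#' Sample Pearson correlation and the two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (as computed by [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, n >= 3, both nonconstant.
#' @return object of class `correlation_result`: `r`, `p_two_tailed`, `n`,
#'   `t`, `df`.
#' @export
pearson_with_p <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_two_tailed = ct$p.value,
                 n = n, t = unname(ct$statistic), df = unname(ct$parameter)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 3, ...) {
  cat("Pearson r = ", signif(x$r, digits), ", p = ", signif(x$p_two_tailed, digits),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Compares `r12 = cor(1, 2)` against `r13 = cor(1, 3)` when variables 2 and
#' 3 are themselves correlated (`r23`), using the Meng-Rosenthal-Rubin
#' (1992) Z on Fisher-transformed correlations:
#' \deqn{Z = (z_{12} - z_{13}) \sqrt{\frac{n - 3}{2 (1 - r_{23}) h}},}
#' with \eqn{\bar r^2 = (r_{12}^2 + r_{13}^2)/2},
#' \eqn{f = \min\{1, (1 - r_{23}) / (2 (1 - \bar r^2))\}} and
#' \eqn{h = (1 - f \bar r^2)/(1 - \bar r^2)}. The reported p-value is the
#' one-tailed upper-tail normal probability of Z (testing `r12 > r13`);
#' swapping `r12` and `r13` negates Z exactly.
#'
#' @param r12,r13 the two correlations sharing variable 1, each strictly
#'   inside (-1, 1).
#' @param r23 correlation between variables 2 and 3, strictly inside (-1, 1).
#' @param n sample size, at least 4.
#' @return object of classes `steiger_test` and `htest` with `statistic`
#'   (Z) and `p.value` (one-tailed).
#' @export
steiger_z <- function(r12, r13, r23, n) {
  for (r in c(r12, r13, r23)) {
    if (!is.finite(r) || abs(r) >= 1)
      stop("correlations must be strictly inside (-1, 1); Fisher transform diverges at |r| = 1")
  }
  if (n < 4) stop("n must be at least 4")
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  rbar2 <- (r12^2 + r13^2) / 2
  f <- min(1, (1 - r23) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  Z <- (z12 - z13) * sqrt((n - 3) / (2 * (1 - r23) * h))
  p <- pnorm(Z, lower.tail = FALSE)
  structure(list(statistic = c(Z = Z), p.value = p,
                 estimate = c(r12 = r12, r13 = r13, r23 = r23),
                 parameter = c(n = n),
                 alternative = "one-tailed (r12 > r13)",
                 method = "Steiger's Z for dependent correlations (Meng-Rosenthal-Rubin)",
                 data.name = sprintf("r12 = %g, r13 = %g, r23 = %g, n = %d",
                                     r12, r13, r23, as.integer(n))),
            class = c("steiger_test", "htest"))
}

#' Multiple regression with standardized coefficients
#'
#' Ordinary least squares of `response` on the columns of `predictors`
#' (via [stats::lm()]), reporting for each predictor the raw coefficient,
#' its standard error, the standardized coefficient
#' `beta * sd(predictor) / sd(response)`, and the two-tailed t p-value —
#' the layout used for brain-behavior covariate regressions.
#'
#' @param response numeric vector.
#' @param predictors data.frame or numeric matrix with named columns.
#' @return object of class `regression_table`: a data.frame with one row
#'   per predictor (intercept first; its standardized beta is `NA`) and
#'   columns `predictor`, `beta`, `se_beta`, `standardized_beta`, `p`, plus
#'   attributes `n`, `r_squared`, `sigma`.
#' @export
ols_regression <- function(response, predictors) {
  X <- as.data.frame(predictors)
  if (is.null(names(X)) || any(names(X) == ""))
    stop("predictors must have names")
  y <- as.numeric(response)
  if (length(y) != nrow(X)) stop("length mismatch between response and predictors")
  n <- length(y)
  if (n <= ncol(X) + 1)
    stop("need n > number of predictors + 1 (n = ", n, ", p = ", ncol(X), ")")
  dat <- cbind(.response = y, X)
  fit <- lm(.response ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    stop("collinear predictor column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  sds <- vapply(X, sd, numeric(1))
  std <- c(NA_real_, ct[-1, 1] * sds[rownames(ct)[-1]] / sd(y))
  out <- data.frame(predictor = c("(Intercept)", rownames(ct)[-1]),
                    beta = ct[, 1], se_beta = ct[, 2],
                    standardized_beta = std, p = ct[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "sigma") <- sm$sigma
  class(out) <- c("regression_table", "data.frame")
  out
}

#' @export
print.regression_table <- function(x, digits = 3, ...) {
  cat("OLS regression (n = ", attr(x, "n"), ", R^2 = ",
      signif(attr(x, "r_squared"), digits), ")\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Two-group comparison: pooled-variance t and Cohen's d
#'
#' Equal-variance two-sample t test (via [stats::t.test()] with
#' `var.equal = TRUE`) plus the standardized mean difference
#' `d = (mean_1 - mean_0) / pooled SD`, with group 1 (e.g. female = 1)
#' minus group 0.
#'
#' @param scores numeric vector.
#' @param group binary (0/1 or two-level) vector; both groups need >= 2
#'   members.
#' @return object of class `two_group_test`: `t`, `df`, `p_two_tailed`,
#'   `cohens_d`, `means` (per group), `n` (per group).
#' @export
two_group_test <- function(scores, group) {
  scores <- as.numeric(scores)
  g <- as.integer(factor(group))
  if (length(unique(g[!is.na(g)])) != 2) stop("group must have exactly 2 levels")
  s1 <- scores[g == 2]   # higher-coded level (e.g. female = 1)
  s0 <- scores[g == 1]
  if (length(s0) < 2 || length(s1) < 2)
    stop("each group needs at least 2 members")
  tt <- stats::t.test(s1, s0, var.equal = TRUE)
  pooled_sd <- sqrt(((length(s1) - 1) * var(s1) + (length(s0) - 1) * var(s0)) /
                      (length(s1) + length(s0) - 2))
  d <- (mean(s1) - mean(s0)) / pooled_sd
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_two_tailed = tt$p.value, cohens_d = d,
                 means = c(group0 = mean(s0), group1 = mean(s1)),
                 n = c(group0 = length(s0), group1 = length(s1))),
            class = "two_group_test")
}

#' @export
print.two_group_test <- function(x, digits = 3, ...) {
  cat("Two-group t (pooled variance): t(", x$df, ") = ", signif(x$t, digits),
      ", p = ", signif(x$p_two_tailed, digits),
      ", Cohen's d = ", signif(x$cohens_d, digits), "\n", sep = "")
  invisible(x)
}

#' ROI identification rate
#'
#' Percentage of subjects in whom the ROI was successfully identified.
#'
#' @param n_identified number of subjects with an identified ROI.
#' @param n_total total number of subjects.
#' @return percentage (0-100).
#' @export
identification_rate <- function(n_identified, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_identified < 0 || n_identified > n_total)
    stop("n_identified must be between 0 and n_total")
  100 * n_identified / n_total
}
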