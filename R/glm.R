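#' Block-design specification
#'
#' Describes a block-design acquisition: repetition time, number of volumes,
#' and a block table (condition, onset, duration in seconds). Conditions are
#' modeled as boxcars convolved with a single-gamma hemodynamic response
#' function (HRF); the temporal derivative of each convolved boxcar can be
#' added as a covariate.
#'
#' The default gamma HRF has mean lag 6 s and dispersion (SD) 3 s
#' (shape = 4, scale = 1.5 s), the conventional single-gamma shape.
#'
#' @param n_volumes number of volumes acquired.
#' @param blocks data.frame with columns `condition`, `onset`, `duration`
#'   (seconds); all blocks must lie within the scan.
#' @param TR repetition time in seconds.
#' @param hrf_shape,hrf_scale gamma HRF shape and scale (seconds); mean lag
#'   is `shape * scale`, dispersion `sqrt(shape) * scale`.
#' @param include_derivatives add a temporal-derivative column per condition.
#' @param conditions declared condition labels; defaults to those present in
#'   `blocks`. Declaring a condition with no blocks is an error at design
#'   construction.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_volumes, blocks, TR = 2,
                        hrf_shape = 4, hrf_scale = 1.5,
                        include_derivatives = TRUE,
                        conditions = NULL) {
  blocks <- as.data.frame(blocks)
  if (nrow(blocks) > 0) {
    stopifnot(all(c("condition", "onset", "duration") %in% names(blocks)))
    total <- TR * n_volumes
    bad <- blocks$onset < 0 | (blocks$onset + blocks$duration) > total
    if (any(bad))
      .stop_cfg("block(s) ", paste(which(bad), collapse = ", "),
                " fall outside [0, ", total, ") s")
  }
  if (is.null(conditions)) conditions <- unique(as.character(blocks$condition))
  spec <- list(TR = TR, n_volumes = as.integer(n_volumes), blocks = blocks,
               hrf_shape = hrf_shape, hrf_scale = hrf_scale,
               include_derivatives = isTRUE(include_derivatives),
               conditions = as.character(conditions))
  class(spec) <- "design_spec"
  spec
}

#' Gamma hemodynamic response function
#'
#' Single-gamma HRF density (unit integral) evaluated at `t` seconds.
#'
#' @param t time in seconds (vector).
#' @param shape,scale gamma parameters; defaults give a 6 s peak lag with
#'   3 s dispersion.
#' @return HRF values at `t`.
#' @export
hrf_gamma <- function(t, shape = 4, scale = 1.5) {
  dgamma(t, shape = shape, scale = scale)
}

#' Build a block-design matrix
#'
#' One column per condition (boxcar convolved with the gamma HRF, sampled at
#' volume acquisition times), optionally followed by its temporal
#' derivative, plus an intercept. Convolution is carried out on a 0.1 s
#' grid; the derivative is the finite-difference slope of the convolved
#' regressor on that grid.
#'
#' @param spec a [design_spec()].
#' @param dt oversampling step in seconds for the convolution grid.
#' @return numeric matrix `n_volumes x regressors` with named columns and a
#'   `condition_columns` attribute mapping each condition to its column
#'   indices. A rank-deficient design (e.g. duplicated condition
#'   definitions) triggers a warning naming the collinear columns.
#' @export
build_design <- function(spec, dt = 0.1) {
  stopifnot(inherits(spec, "design_spec"))
  nT <- spec$n_volumes
  vol_times <- (seq_len(nT) - 1) * spec$TR
  fine_t <- seq(0, spec$TR * nT, by = dt)
  hrf <- hrf_gamma(seq(0, 32, by = dt), spec$hrf_shape, spec$hrf_scale)

  cols <- list()
  cond_cols <- list()
  for (cond in spec$conditions) {
    b <- spec$blocks[spec$blocks$condition == cond, , drop = FALSE]
    if (nrow(b) == 0)
      .stop_cfg("condition '", cond, "' is declared but has no blocks")
    boxcar <- numeric(length(fine_t))
    for (j in seq_len(nrow(b))) {
      boxcar[fine_t >= b$onset[j] & fine_t < b$onset[j] + b$duration[j]] <- 1
    }
    conv <- .convolve_open(boxcar, hrf) * dt   # discrete approx of continuous conv
    conv <- conv[seq_along(fine_t)]
    reg <- conv[match(round(vol_times, 6), round(fine_t, 6))]
    cols[[cond]] <- reg
    cond_cols[[cond]] <- length(cols)
    if (spec$include_derivatives) {
      dconv <- c(diff(conv) / dt, 0)
      cols[[paste0(cond, "_deriv")]] <- dconv[match(round(vol_times, 6), round(fine_t, 6))]
    }
  }
  cols[["(Intercept)"]] <- rep(1, nT)
  X <- do.call(cbind, cols)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("design is rank deficient; collinear column(s): ",
            paste(dropped, collapse = ", "))
  }
  attr(X, "condition_columns") <- cond_cols
  X
}

# full linear convolution by direct summation over the kernel (small kernels;
# avoids FFT edge conventions)
.convolve_open <- function(x, k) {
  n <- length(x); m <- length(k)
  out <- numeric(n + m - 1)
  for (j in seq_len(m)) {
    out[j:(j + n - 1)] <- out[j:(j + n - 1)] + k[j] * x
  }
  out
}

#' Fit a voxelwise general linear model
#'
#' Ordinary least squares per voxel: `Y = X beta + noise`, one row of `Y`
#' per voxel. Nuisance covariates (e.g. motion parameters) are appended to
#' the design before fitting.
#'
#' @param timeseries numeric matrix, voxels x time.
#' @param design design matrix, time x regressors (e.g. [build_design()]).
#' @param nuisance optional time x covariate matrix appended to the design.
#' @return object of class `glm_fit`: `betas` (voxels x regressors),
#'   `sigma2` (residual variance per voxel), `df` (residual degrees of
#'   freedom `n_volumes - rank`), `design`, and the unscaled coefficient
#'   covariance `xtx_inv`.
#' @export
fit_glm <- function(timeseries, design, nuisance = NULL) {
  Y <- as.matrix(timeseries)
  X <- as.matrix(design)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == nrow(X))
    colnames(nuisance) <- colnames(nuisance) %||% paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  if (ncol(Y) != nrow(X))
    stop("time dimensions disagree: timeseries has ", ncol(Y),
         " volumes, design has ", nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  betas <- t(qr.coef(qrX, t(Y)))            # voxels x regressors
  fitted <- betas %*% t(X)
  res <- Y - fitted
  df <- nrow(X) - qrX$rank
  sigma2 <- rowSums(res^2) / df
  # an exact fit leaves only rounding error; call that zero variance so the
  # contrast machinery reports an explicit infinite statistic, not noise
  sigma2[sigma2 < 1e-20 * (rowMeans(fitted^2) + 1)] <- 0
  structure(list(betas = betas, sigma2 = sigma2, df = df,
                 design = X, xtx_inv = chol2inv(chol(crossprod(X)))),
            class = "glm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.glm_fit <- function(x, ...) {
  cat("Voxelwise GLM fit:", nrow(x$betas), "voxels,",
      ncol(x$betas), "regressors, residual df =", x$df, "\n")
  invisible(x)
}

#' Contrast Z statistic per voxel
#'
#' Computes `t = (c' beta) / SE(c' beta)` per voxel and converts to a
#' standard-normal-scale Z by matching the two-sided t p-value through the
#' normal quantile, preserving sign. This is the scale on which
#' supra-threshold ROIs (Z > 2.3, p < 0.01 uncorrected) are defined.
#'
#' A voxel with zero residual variance and a nonzero contrast yields an
#' explicit `Inf` (with the contrast's sign) and a warning.
#'
#' @param fit a [fit_glm()] result.
#' @param weights contrast weight vector, one entry per regressor.
#' @return list with `t`, `z` (per-voxel vectors) and `df`.
#' @export
contrast_z <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  w <- as.numeric(weights)
  if (length(w) != ncol(fit$betas))
    stop("contrast length ", length(w), " != number of regressors ", ncol(fit$betas))
  cb <- drop(fit$betas %*% w)
  # a contrast at rounding level relative to the betas it combines is zero
  cb[abs(cb) < 1e-10 * drop(abs(fit$betas) %*% abs(w))] <- 0
  cvar <- drop(t(w) %*% fit$xtx_inv %*% w) * fit$sigma2
  tstat <- cb / sqrt(cvar)
  if (any(!is.finite(tstat) & cb != 0)) {
    warning("zero residual variance with nonzero contrast: infinite statistic")
    tstat[!is.finite(tstat) & cb != 0] <- sign(cb[!is.finite(tstat) & cb != 0]) * Inf
  }
  tstat[!is.finite(tstat) & cb == 0] <- 0
  list(t = tstat, z = t_to_z(tstat, fit$df), df = fit$df)
}

#' Convert t statistics to standard-normal Z scores
#'
#' Sign-preserving p-value matching: the upper-tail probability of `|t|`
#' under the t distribution is mapped through the standard normal quantile
#' (computed on the log scale for numerical stability in the far tail).
#'
#' @param t t statistics (vector).
#' @param df degrees of freedom.
#' @return Z scores of the same sign as `t`.
#' @export
t_to_z <- function(t, df) {
  z <- sign(t) * qnorm(pt(abs(t), df, lower.tail = FALSE, log.p = TRUE),
                       lower.tail = FALSE, log.p = TRUE)
  z[is.infinite(t)] <- t[is.infinite(t)]
  z
}
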