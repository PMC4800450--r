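#' Pipeline run configuration
#'
#' Bundles everything a full analysis run needs: the input mode, the
#' simulation config (synthetic mode) or input directory (patterns-csv
#' mode), the (neural measure, behavior) pairs to analyze, the covariate
#' sets for the regressions, and the cross-validation settings.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"patterns_csv"` (read a
#'   cohort written by [write_cohort()]).
#' @param sim a [sim_config()] (synthetic mode).
#' @param input_dir cohort directory (patterns_csv mode).
#' @param analyses data.frame with columns `measure`, `behavior`: the
#'   correlation/prediction pairs. Defaults to the 2 x 2 battery of
#'   \{selectivity, between-category dissimilarity\} x \{expression score,
#'   identity accuracy\}.
#' @param regressions named list of formulas-as-lists: each element has
#'   `response` and `predictors` (character vectors of column names).
#'   Defaults mirror the covariate regressions of the analysis battery:
#'   expression ~ selectivity + dissimilarity + gender; identity ~
#'   dissimilarity + selectivity + flower accuracy + gender; and the noise
#'   control identity ~ between-dissimilarity + within-dissimilarity.
#' @param k CV folds; `B` permutation shuffles.
#' @param B number of permutation shuffles.
#' @param balance_alpha fold-balance threshold.
#' @param seed master seed for fold assignment and permutations.
#' @param centering_categories see [between_category_dissimilarity()].
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "patterns_csv"),
                       sim = sim_config(), input_dir = NULL,
                       analyses = NULL, regressions = NULL,
                       k = 4, B = 5000, balance_alpha = 0.05, seed = 1L,
                       centering_categories = NULL) {
  mode <- match.arg(mode)
  if (mode == "patterns_csv" && is.null(input_dir))
    .stop_cfg("patterns_csv mode requires input_dir")
  if (is.null(analyses)) {
    analyses <- expand.grid(measure = c("selectivity", "dissim_between"),
                            behavior = c("eyes_score", "face_acc"),
                            stringsAsFactors = FALSE)
  }
  if (is.null(regressions)) {
    regressions <- list(
      expression = list(response = "eyes_score",
                        predictors = c("dissim_between", "selectivity", "gender")),
      identity = list(response = "face_acc",
                      predictors = c("dissim_between", "selectivity",
                                     "flower_acc", "gender")),
      identity_noise_control = list(response = "face_acc",
                                    predictors = c("dissim_between", "dissim_within"))
    )
  }
  if (mode == "synthetic") {
    stopifnot(inherits(sim, "sim_config"))
    if (sim$n_subjects < 2 * k)
      .stop_cfg("n_subjects (", sim$n_subjects, ") must be at least 2k (",
                2 * k, ") for ", k, "-fold cross-validation")
  }
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 analyses = analyses, regressions = regressions,
                 k = as.integer(k), B = as.integer(B),
                 balance_alpha = balance_alpha, seed = as.integer(seed),
                 centering_categories = centering_categories),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort acquisition (synthetic or from disk), per-subject
#' neural-code measures, the correlation battery, dependent-correlation
#' comparisons, covariate regressions, and balanced cross-validated
#' prediction with permutation significance. Fully deterministic given the
#' seeds in `config`.
#'
#' @param config a [run_config()].
#' @return object of class `coding_analysis`: `subjects` (table with
#'   measures appended), `correlations`, `steiger`, `regressions`,
#'   `cv`, `gender_test`, `exclusions` (subjects without measures, with
#'   reasons), `identification` (count + rate), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$sim)
    subjects <- cohort$subjects
    patterns <- cohort$patterns
  } else {
    cohort <- read_cohort(config$input_dir)
    subjects <- cohort$subjects
    patterns <- cohort$patterns
  }
  n_input <- nrow(subjects)

  # per-subject neural measures; a subject whose patterns are missing or
  # degenerate is excluded listwise, with the reason logged
  meas <- matrix(NA_real_, n_input, 3,
                 dimnames = list(NULL, c("selectivity", "dissim_between",
                                         "dissim_within")))
  excl_reason <- character(n_input)
  for (i in seq_len(n_input)) {
    pm <- patterns[[subjects$subject_id[i]]]
    if (is.null(pm)) {
      excl_reason[i] <- "ROI not identified"
      next
    }
    m <- tryCatch(
      neural_measures(pm, centering_categories =
                        config$centering_categories %||% pm$categories),
      error = function(e) conditionMessage(e))
    if (is.character(m)) excl_reason[i] <- m else meas[i, ] <- m
  }
  subjects <- cbind(subjects, as.data.frame(meas))
  analyzed <- excl_reason == ""
  exclusions <- data.frame(subject_id = subjects$subject_id[!analyzed],
                           reason = excl_reason[!analyzed],
                           stringsAsFactors = FALSE)
  tab <- subjects[analyzed, , drop = FALSE]
  if (nrow(tab) + nrow(exclusions) != n_input)
    stop("subject accounting error: analyzed + excluded != input")
  identification <- list(n_identified = nrow(tab), n_total = n_input,
                         rate = identification_rate(nrow(tab), n_input))

  # correlation battery (+ the within-category noise-control correlation)
  pairs <- rbind(config$analyses,
                 data.frame(measure = "dissim_within", behavior = "face_acc",
                            stringsAsFactors = FALSE))
  correlations <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
    res <- pearson_with_p(tab[[pairs$measure[j]]], tab[[pairs$behavior[j]]])
    data.frame(measure = pairs$measure[j], behavior = pairs$behavior[j],
               n = res$n, r = res$r, p = res$p_two_tailed,
               stringsAsFactors = FALSE)
  }))

  # dependent-correlation comparisons: which neural code correlates more
  # strongly with each behavior, given the codes' own intercorrelation
  r23 <- cor(tab$selectivity, tab$dissim_between)
  steiger <- list(
    identity = steiger_z(cor(tab$dissim_between, tab$face_acc),
                         cor(tab$selectivity, tab$face_acc), r23, nrow(tab)),
    expression = steiger_z(cor(tab$selectivity, tab$eyes_score),
                           cor(tab$dissim_between, tab$eyes_score), r23, nrow(tab))
  )

  regressions <- lapply(config$regressions, function(spec) {
    missing <- setdiff(c(spec$response, spec$predictors), names(tab))
    if (length(missing))
      .stop_cfg("regression references missing column(s): ",
                paste(missing, collapse = ", "))
    ols_regression(tab[[spec$response]], tab[spec$predictors])
  })

  gender_test <- two_group_test(tab$eyes_score, tab$gender)

  cv <- do.call(rbind, lapply(seq_len(nrow(config$analyses)), function(j) {
    m <- config$analyses$measure[j]; b <- config$analyses$behavior[j]
    res <- cv_predictability(tab[[m]], tab[[b]], k = config$k, B = config$B,
                             balance_alpha = config$balance_alpha,
                             seed = config$seed + j)
    data.frame(measure = m, behavior = b, n = res$n,
               r_prediction_observation = res$r_prediction_observation,
               p_permutation = res$p_permutation, B = res$B,
               seed = res$seed, stringsAsFactors = FALSE)
  }))

  structure(list(subjects = subjects, analyzed = tab,
                 correlations = correlations, steiger = steiger,
                 regressions = regressions, cv = cv,
                 gender_test = gender_test, exclusions = exclusions,
                 identification = identification, config = config),
            class = "coding_analysis")
}

#' @export
print.coding_analysis <- function(x, digits = 3, ...) {
  cat("Neural-code / behavior analysis:", nrow(x$analyzed), "of",
      x$identification$n_total, "subjects analyzed (",
      sprintf("%.0f%%", x$identification$rate), "ROI identification)\n\n")
  cat("Correlations (measure x behavior):\n")
  print.data.frame(format(x$correlations, digits = digits), row.names = FALSE)
  cat("\nDependent-correlation comparisons:\n")
  for (nm in names(x$steiger)) {
    s <- x$steiger[[nm]]
    cat(sprintf("  %s: Z = %.2f, one-tail p = %.3f\n",
                nm, s$statistic, s$p.value))
  }
  cat("\nCross-validated prediction:\n")
  print.data.frame(format(x$cv, digits = digits), row.names = FALSE)
  if (nrow(x$exclusions))
    cat("\nExcluded subjects:", nrow(x$exclusions), "(see $exclusions)\n")
  invisible(x)
}

#' @export
summary.coding_analysis <- function(object, ...) {
  print(object, ...)
  cat("\nGender difference on expression score:\n  ")
  print(object$gender_test)
  cat("\nRegressions:\n")
  for (nm in names(object$regressions)) {
    cat("--", nm, "--\n")
    print(object$regressions[[nm]])
  }
  invisible(object)
}

#' @export
plot.coding_analysis <- function(x, ...) {
  pairs <- x$config$analyses
  old <- par(mfrow = c(2, ceiling(nrow(pairs) / 2)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (j in seq_len(nrow(pairs))) {
    m <- pairs$measure[j]; b <- pairs$behavior[j]
    r <- x$correlations$r[x$correlations$measure == m &
                            x$correlations$behavior == b][1]
    plot(x$analyzed[[m]], x$analyzed[[b]], xlab = m, ylab = b,
         main = sprintf("r = %.2f", r), ...)
    abline(lm(x$analyzed[[b]] ~ x$analyzed[[m]]), lty = 2)
  }
  invisible(x)
}

#' Write the analysis report to disk
#'
#' Emits tidy CSV tables (correlations, Steiger comparisons, one CSV per
#' regression, CV results, exclusion log, subject table with measures) plus
#' a human-readable `report.txt` laid out like the analysis battery:
#' correlation matrix with n, regression tables with beta / SE beta /
#' standardized beta / p per predictor, and the CV table. Output is
#' deterministic (no timestamps).
#'
#' @param analysis a `coding_analysis` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
make_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "coding_analysis"))
  required <- c("correlations", "steiger", "regressions", "cv")
  for (nm in required) {
    if (is.null(analysis[[nm]]) ||
        (is.data.frame(analysis[[nm]]) && nrow(analysis[[nm]]) == 0))
      stop("cannot write report: missing or empty table '", nm, "'")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(analysis$correlations, file.path(dir, "correlations.csv"),
            row.names = FALSE)
  st <- do.call(rbind, lapply(names(analysis$steiger), function(nm) {
    s <- analysis$steiger[[nm]]
    data.frame(comparison = nm, r12 = s$estimate["r12"], r13 = s$estimate["r13"],
               r23 = s$estimate["r23"], n = s$parameter["n"],
               Z = s$statistic, p_one_tailed = s$p.value, row.names = NULL)
  }))
  write.csv(st, file.path(dir, "steiger.csv"), row.names = FALSE)
  for (nm in names(analysis$regressions)) {
    write.csv(as.data.frame(analysis$regressions[[nm]]),
              file.path(dir, paste0("regression_", nm, ".csv")),
              row.names = FALSE)
  }
  write.csv(analysis$cv, file.path(dir, "cv.csv"), row.names = FALSE)
  write.csv(analysis$exclusions, file.path(dir, "exclusions.csv"),
            row.names = FALSE)
  write.csv(analysis$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)

  txt <- file.path(dir, "report.txt")
  con <- file(txt, open = "wt")
  on.exit(close(con))
  sink(con)
  summary(analysis)
  sink()
  invisible(dir)
}

#' Neural-code measures from a BOLD volume
#'
#' Convenience GLM + ROI stage for volumetric input: fits the block-design
#' GLM to a 4-D time series, computes the faces-versus-objects contrast Z
#' map, extracts the contiguous supra-threshold ROI around a seed, and
#' (when per-run designs are supplied) returns the ROI pattern matrix.
#'
#' @param bold 4-D array (x, y, z, time).
#' @param design a [design_spec()] covering all categories.
#' @param roi_seed seed voxel for [extract_roi()].
#' @param threshold,neighborhood,min_size,search_radius ROI extraction
#'   parameters.
#' @param contrast character 2-vector: the two conditions contrasted
#'   (positive, negative), default faces > objects.
#' @return list with `fit` (voxelwise `glm_fit`), `zmap` (3-D array),
#'   `roi` (`roi_mask`), and `selectivity` (mean ROI Z; `NA` when the ROI
#'   is not identified).
#' @export
volume_measures <- function(bold, design, roi_seed, threshold = 2.3,
                            neighborhood = 26, min_size = 1, search_radius = 2,
                            contrast = c("faces", "objects")) {
  dm <- dim(bold)
  stopifnot(length(dm) == 4)
  Y <- matrix(bold, nrow = prod(dm[1:3]), ncol = dm[4])
  X <- build_design(design)
  fit <- fit_glm(Y, X)
  w <- numeric(ncol(X))
  names(w) <- colnames(X)
  if (!all(contrast %in% colnames(X)))
    stop("contrast conditions not found in design: ",
         paste(setdiff(contrast, colnames(X)), collapse = ", "))
  w[contrast[1]] <- 1
  w[contrast[2]] <- -1
  cz <- contrast_z(fit, w)
  zmap <- array(cz$z, dim = dm[1:3])
  roi <- extract_roi(zmap, roi_seed, threshold = threshold,
                     neighborhood = neighborhood, min_size = min_size,
                     search_radius = search_radius)
  sel <- if (roi$identified) overall_selectivity(cz$z, roi) else NA_real_
  list(fit = fit, zmap = zmap, roi = roi, selectivity = sel)
}
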