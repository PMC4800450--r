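#' Pattern matrix container
#'
#' Per-subject ROI voxel responses: a `categories x runs x voxels` array of
#' beta estimates plus a per-voxel faces-versus-objects contrast Z vector.
#'
#' @param betas numeric 3-D array `[category, run, voxel]` with category
#'   dimnames.
#' @param contrast_z numeric vector of per-voxel contrast Z scores, same
#'   voxel count as `betas`.
#' @return object of class `pattern_matrix` with components `betas`,
#'   `contrast_z`, `categories`, `n_runs`, `n_voxels`.
#' @export
pattern_matrix <- function(betas, contrast_z) {
  stopifnot(is.array(betas), length(dim(betas)) == 3)
  categories <- dimnames(betas)[[1]]
  if (is.null(categories))
    stop("betas must carry category dimnames on its first dimension")
  n_voxels <- dim(betas)[3]
  if (length(contrast_z) != n_voxels)
    stop("contrast_z length (", length(contrast_z),
         ") != voxel count (", n_voxels, ")")
  if (n_voxels < 2)
    stop("at least 2 voxels are required for correlation-based measures")
  structure(list(betas = betas, contrast_z = as.numeric(contrast_z),
                 categories = categories, n_runs = dim(betas)[2],
                 n_voxels = n_voxels),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat("Pattern matrix:", x$n_voxels, "voxels x", x$n_runs, "runs x",
      length(x$categories), "categories (",
      paste(x$categories, collapse = ", "), ")\n")
  invisible(x)
}

#' Write / read a pattern matrix as CSV
#'
#' Plain-text format: rows = voxels; one column per `<category>_run<r>`
#' beta, plus a final `contrast_z` column.
#'
#' @param pm a [pattern_matrix()].
#' @param path file path.
#' @return `path` invisibly (write) or a `pattern_matrix` (read).
#' @export
write_pattern_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "pattern_matrix"))
  cols <- list()
  for (cat in pm$categories) {
    for (r in seq_len(pm$n_runs)) {
      cols[[paste0(cat, "_run", r)]] <- pm$betas[cat, r, ]
    }
  }
  cols[["contrast_z"]] <- pm$contrast_z
  write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_matrix
#' @export
read_pattern_matrix <- function(path) {
  df <- read.csv(path)
  beta_cols <- grep("_run[0-9]+$", names(df), value = TRUE)
  cats <- unique(sub("_run[0-9]+$", "", beta_cols))
  runs <- sort(unique(as.integer(sub("^.*_run", "", beta_cols))))
  nv <- nrow(df)
  betas <- array(0, dim = c(length(cats), length(runs), nv),
                 dimnames = list(cats, NULL, NULL))
  for (cat in cats) for (r in runs) betas[cat, r, ] <- df[[paste0(cat, "_run", r)]]
  pattern_matrix(betas, df$contrast_z)
}

.neighborhood_offsets <- function(neighborhood) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  switch(as.character(neighborhood),
         "6"  = off[rowSums(abs(off)) == 1, , drop = FALSE],
         "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
         "26" = off,
         stop("neighborhood must be one of 6, 18, 26"))
}

#' Extract a contiguous supra-threshold ROI around a seed
#'
#' Thresholds a 3-D Z map (default Z > 2.3, i.e. p < 0.01 uncorrected) and
#' returns the connected component of supra-threshold voxels containing the
#' seed, or the component containing the nearest supra-threshold voxel
#' within `search_radius` of the seed. Connectivity is breadth-first over
#' the declared neighborhood system (6, 18 or 26 neighbors).
#'
#' An ROI that cannot be identified (no supra-threshold voxel within reach,
#' or a component smaller than `min_size`) is an explicit, non-error
#' outcome: the returned mask has `identified = FALSE` and zero voxels.
#' Subjects without an identifiable ROI are excluded listwise downstream.
#'
#' @param zmap numeric 3-D array of Z scores.
#' @param seed integer 3-vector, seed voxel coordinate (1-based).
#' @param threshold Z threshold; voxels must strictly exceed it.
#' @param neighborhood connectivity: 6, 18 or 26.
#' @param min_size minimum component size in voxels.
#' @param search_radius Chebyshev radius around the seed searched for a
#'   supra-threshold voxel when the seed itself is below threshold.
#' @return object of class `roi_mask`: `identified` (logical), `voxels`
#'   (n x 3 integer matrix of coordinates), `indices` (linear indices),
#'   `size`, `seed`, `threshold`, `dim`.
#' @export
extract_roi <- function(zmap, seed, threshold = 2.3, neighborhood = 26,
                        min_size = 1, search_radius = 2) {
  stopifnot(is.array(zmap), length(dim(zmap)) == 3)
  dm <- dim(zmap)
  seed <- as.integer(seed)
  if (length(seed) != 3 || any(seed < 1) || any(seed > dm))
    stop("seed coordinate out of volume bounds")
  supra <- zmap > threshold

  not_identified <- function() {
    structure(list(identified = FALSE,
                   voxels = matrix(integer(0), 0, 3), indices = integer(0),
                   size = 0L, seed = seed, threshold = threshold, dim = dm),
              class = "roi_mask")
  }

  # locate a supra-threshold start voxel at or near the seed
  start <- NULL
  if (supra[seed[1], seed[2], seed[3]]) {
    start <- seed
  } else if (search_radius > 0) {
    idx <- which(supra, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      cheb <- pmax(abs(idx[, 1] - seed[1]),
                   pmax(abs(idx[, 2] - seed[2]), abs(idx[, 3] - seed[3])))
      eligible <- which(cheb <= search_radius)
      if (length(eligible) > 0) {
        # nearest by Euclidean distance, ties broken by linear index
        d2 <- rowSums((idx[eligible, , drop = FALSE] -
                         matrix(seed, length(eligible), 3, byrow = TRUE))^2)
        start <- idx[eligible[which.min(d2)], ]
      }
    }
  }
  if (is.null(start)) return(not_identified())

  off <- .neighborhood_offsets(neighborhood)
  visited <- array(FALSE, dim = dm)
  queue <- matrix(start, ncol = 3)
  visited[start[1], start[2], start[3]] <- TRUE
  members <- list()
  while (nrow(queue) > 0) {
    members[[length(members) + 1]] <- queue
    nxt <- list()
    for (i in seq_len(nrow(queue))) {
      nb <- sweep(off, 2, queue[i, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      for (j in seq_len(nrow(nb))) {
        v <- nb[j, ]
        if (!visited[v[1], v[2], v[3]] && supra[v[1], v[2], v[3]]) {
          visited[v[1], v[2], v[3]] <- TRUE
          nxt[[length(nxt) + 1]] <- v
        }
      }
    }
    queue <- if (length(nxt)) do.call(rbind, nxt) else matrix(integer(0), 0, 3)
  }
  vox <- do.call(rbind, members)
  storage.mode(vox) <- "integer"
  colnames(vox) <- c("x", "y", "z")
  if (nrow(vox) < min_size) return(not_identified())
  indices <- unname(vox[, 1] + dm[1] * (vox[, 2] - 1) + dm[1] * dm[2] * (vox[, 3] - 1))
  ord <- order(indices)
  structure(list(identified = TRUE, voxels = vox[ord, , drop = FALSE],
                 indices = indices[ord], size = nrow(vox),
                 seed = seed, threshold = threshold, dim = dm),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  if (x$identified) {
    cat("ROI: ", x$size, " voxels (Z > ", x$threshold, ", seed ",
        paste(x$seed, collapse = ","), ")\n", sep = "")
  } else {
    cat("ROI not identified (no supra-threshold component near seed ",
        paste(x$seed, collapse = ","), " at Z > ", x$threshold, ")\n", sep = "")
  }
  invisible(x)
}

#' Overall selectivity: mean contrast Z across ROI voxels
#'
#' The univariate ("localized") neural-code measure: the arithmetic mean of
#' the faces-versus-objects contrast Z over all ROI voxels.
#'
#' @param patterns a [pattern_matrix()] (already restricted to the ROI), or
#'   a numeric vector of per-voxel Z scores.
#' @param mask optional [extract_roi()] mask; when supplied with a full
#'   volume's Z vector, only mask voxels enter the mean.
#' @return mean Z (scalar).
#' @export
overall_selectivity <- function(patterns, mask = NULL) {
  z <- if (inherits(patterns, "pattern_matrix")) patterns$contrast_z else as.numeric(patterns)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "roi_mask"))
    if (!mask$identified || mask$size == 0) stop("empty ROI mask")
    z <- z[mask$indices]
  }
  if (length(z) == 0) stop("no voxels to average")
  mean(z)
}

# run-averaged beta vector for one category
.category_pattern <- function(pm, category) {
  if (!category %in% pm$categories)
    stop("unknown category '", category, "'")
  colMeans(matrix(pm$betas[category, , ], nrow = pm$n_runs))
}

#' Between-category pattern dissimilarity (1 - r, mean pattern removed)
#'
#' The multivariate ("distributed") neural-code measure: one minus the
#' Pearson correlation between the spatial response patterns of two
#' categories. Betas are averaged across runs per category; before the
#' correlation, the voxelwise mean pattern across `centering_categories` is
#' subtracted from each category's vector (mean-pattern / cocktail-blank
#' removal).
#'
#' Centering over exactly the two compared categories is algebraically
#' degenerate — the centered vectors are exact negatives of each other, so
#' the dissimilarity is forced to 2 regardless of the data — and is
#' therefore rejected unless `allow_degenerate = TRUE` (useful only for
#' demonstrating the degeneracy).
#'
#' @param patterns a [pattern_matrix()].
#' @param category_a,category_b the two categories to compare.
#' @param centering_categories categories defining the mean pattern;
#'   defaults to all categories in `patterns`. `NULL` disables centering.
#' @param allow_degenerate permit the degenerate two-category centering set.
#' @return dissimilarity in \[0, 2\].
#' @export
between_category_dissimilarity <- function(patterns,
                                           category_a = "faces",
                                           category_b = "objects",
                                           centering_categories = patterns$categories,
                                           allow_degenerate = FALSE) {
  stopifnot(inherits(patterns, "pattern_matrix"))
  va <- .category_pattern(patterns, category_a)
  vb <- .category_pattern(patterns, category_b)
  if (!is.null(centering_categories)) {
    cset <- unique(centering_categories)
    if (!all(cset %in% patterns$categories))
      stop("centering categories missing from patterns: ",
           paste(setdiff(cset, patterns$categories), collapse = ", "))
    if (setequal(cset, c(category_a, category_b)) && !allow_degenerate)
      stop("centering over exactly the two compared categories is degenerate: ",
           "the centered vectors are exact negatives and the dissimilarity ",
           "is forced to 2; use >= 3 categories")
    if (length(cset) < 2) stop("centering needs at least 2 categories")
    m <- Reduce(`+`, lapply(cset, .category_pattern, pm = patterns)) / length(cset)
    va <- va - m
    vb <- vb - m
  }
  if (sd(va) == 0 || sd(vb) == 0)
    stop("zero-variance pattern vector: correlation undefined")
  .clamp02(1 - cor(va, vb))
}

#' Within-category pattern dissimilarity (split-run reliability)
#'
#' One minus the Pearson correlation between two independent runs' beta
#' patterns for the same category — an inverse test-retest reliability used
#' as an index of measurement noise. No cross-category centering is applied.
#'
#' @param patterns a [pattern_matrix()].
#' @param category the category whose runs are compared.
#' @param run_a,run_b the two (distinct) run indices.
#' @return dissimilarity in \[0, 2\].
#' @export
within_category_dissimilarity <- function(patterns, category = "faces",
                                          run_a = 1, run_b = 2) {
  stopifnot(inherits(patterns, "pattern_matrix"))
  if (!category %in% patterns$categories) stop("unknown category '", category, "'")
  if (run_a == run_b) stop("run_a and run_b must differ")
  if (max(run_a, run_b) > patterns$n_runs || min(run_a, run_b) < 1)
    stop("run index out of range (patterns have ", patterns$n_runs, " runs)")
  va <- patterns$betas[category, run_a, ]
  vb <- patterns$betas[category, run_b, ]
  if (sd(va) == 0 || sd(vb) == 0)
    stop("zero-variance run vector: correlation undefined")
  .clamp02(1 - cor(va, vb))
}

#' All three neural-code measures for one subject
#'
#' @param patterns a [pattern_matrix()].
#' @param category_a,category_b categories for the between-category measure
#'   and the selectivity contrast.
#' @param centering_categories see [between_category_dissimilarity()].
#' @param reliability_runs length-2 run indices for the within-category
#'   measure.
#' @return named numeric vector: `selectivity`, `dissim_between`,
#'   `dissim_within`.
#' @export
neural_measures <- function(patterns, category_a = "faces", category_b = "objects",
                            centering_categories = patterns$categories,
                            reliability_runs = c(1, 2)) {
  c(selectivity = overall_selectivity(patterns),
    dissim_between = between_category_dissimilarity(
      patterns, category_a, category_b, centering_categories),
    dissim_within = within_category_dissimilarity(
      patterns, category_a, reliability_runs[1], reliability_runs[2]))
}
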