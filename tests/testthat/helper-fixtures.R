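# Small in-code fixtures shared across test files.

# pattern_matrix from a list of category -> runs x voxels matrices
make_pm <- function(cat_runs, contrast_z = NULL) {
  cats <- names(cat_runs)
  n_runs <- nrow(cat_runs[[1]])
  nv <- ncol(cat_runs[[1]])
  betas <- array(0, dim = c(length(cats), n_runs, nv),
                 dimnames = list(cats, NULL, NULL))
  for (cc in cats) betas[cc, , ] <- cat_runs[[cc]]
  if (is.null(contrast_z)) contrast_z <- rep(0, nv)
  pattern_matrix(betas, contrast_z)
}

# pattern_matrix with each run duplicating the category's single pattern
make_pm_const_runs <- function(cat_patterns, n_runs = 2, contrast_z = NULL) {
  make_pm(lapply(cat_patterns,
                 function(v) matrix(v, n_runs, length(v), byrow = TRUE)),
          contrast_z)
}

# two-condition block design used by GLM and BOLD tests
toy_design <- function(n_volumes = 60, TR = 2, include_derivatives = FALSE) {
  design_spec(
    n_volumes = n_volumes, TR = TR,
    blocks = data.frame(
      condition = c("faces", "objects", "faces", "objects"),
      onset = c(10, 40, 70, 100),
      duration = 18),
    include_derivatives = include_derivatives)
}

# a small quick cohort for pipeline-level tests
quick_sim <- function(seed = 1, n_subjects = 48, n_voxels = 40) {
  sim_config(n_subjects = n_subjects, n_voxels = n_voxels, seed = seed)
}
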