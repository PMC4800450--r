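#' Simulation configuration for a synthetic cohort
#'
#' Defines the population a synthetic cohort is drawn from: two latent
#' neural channels per subject (a univariate amplitude driving mean face
#' activation, and a pattern-separation angle driving the face-vs-object
#' dissimilarity), behavioral scores linearly linked to those channels with
#' planted population correlations, and a standardized gender difference on
#' the expression score. The two brain-behavior channels are generated
#' independently, so any double dissociation observed downstream is
#' structural rather than incidental.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_voxels ROI size in voxels.
#' @param n_runs number of scanning runs (at least 2; run 1 vs run 2 feeds
#'   the within-category reliability measure).
#' @param categories ordered category labels; the first is the preferred
#'   category (faces), the second the contrast baseline (objects). At least
#'   3 categories are required for mean-pattern removal downstream.
#' @param rho_selectivity_expression planted population correlation between
#'   the latent mean face activation and the expression (Eyes Test) score;
#'   strictly inside (-1, 1).
#' @param rho_dissim_identity planted population correlation between the
#'   latent pattern separation and the identity (old/new face) accuracy;
#'   strictly inside (-1, 1).
#' @param gender_effect_d standardized (Cohen's d) female-minus-male
#'   difference on the expression score.
#' @param noise_sd per-run, per-voxel Gaussian measurement noise SD, on the
#'   scale of unit-RMS spatial patterns.
#' @param seed integer RNG seed; identical configs give identical cohorts.
#' @param p_female probability a subject is female (gender coded female = 1).
#' @param eyes_mean,eyes_sd population mean/SD of the Eyes Test score
#'   (0-36 integer scale).
#' @param face_acc_mean,face_acc_sd population mean/SD of old/new face
#'   accuracy on \[0, 1\].
#' @param flower_acc_mean,flower_acc_sd population mean/SD of old/new flower
#'   accuracy on \[0, 1\].
#' @param amplitude_mean,amplitude_sd population mean/SD of the latent face
#'   amplitude (units of contrast Z).
#' @param separation_mean,separation_sd population mean/SD of the latent
#'   pattern separation, a target dissimilarity bounded in \[0, 2\]
#'   (values outside are clipped and the clipping rate logged).
#' @param rho_behavior planted correlation between the expression and
#'   identity scores beyond what the (independent) neural channels induce;
#'   default 0.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_subjects = 165, n_voxels = 200, n_runs = 3,
                       categories = c("faces", "objects", "scenes", "scrambled"),
                       rho_selectivity_expression = 0.22,
                       rho_dissim_identity = 0.27,
                       gender_effect_d = 0.58,
                       noise_sd = 0.3,
                       seed = 1L,
                       p_female = 0.6,
                       eyes_mean = 24, eyes_sd = 3,
                       face_acc_mean = 0.78, face_acc_sd = 0.09,
                       flower_acc_mean = 0.81, flower_acc_sd = 0.08,
                       amplitude_mean = 3, amplitude_sd = 1,
                       separation_mean = 0.8, separation_sd = 0.25,
                       rho_behavior = 0) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_voxels = as.integer(n_voxels),
              n_runs = as.integer(n_runs), categories = as.character(categories),
              rho_selectivity_expression = rho_selectivity_expression,
              rho_dissim_identity = rho_dissim_identity,
              gender_effect_d = gender_effect_d, noise_sd = noise_sd,
              seed = as.integer(seed), p_female = p_female,
              eyes_mean = eyes_mean, eyes_sd = eyes_sd,
              face_acc_mean = face_acc_mean, face_acc_sd = face_acc_sd,
              flower_acc_mean = flower_acc_mean, flower_acc_sd = flower_acc_sd,
              amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
              separation_mean = separation_mean, separation_sd = separation_sd,
              rho_behavior = rho_behavior)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 1) .stop_cfg("n_subjects must be a positive integer")
  if (cfg$n_voxels < 2) .stop_cfg("n_voxels must be at least 2 (correlation-based measures need >= 2 voxels)")
  if (cfg$n_runs < 2) .stop_cfg("n_runs must be >= 2 (within-category reliability needs two runs)")
  if (length(cfg$categories) < 3)
    .stop_cfg("at least 3 categories are required (mean-pattern removal over 2 is degenerate)")
  if (anyDuplicated(cfg$categories)) .stop_cfg("categories must be distinct labels")
  for (nm in c("rho_selectivity_expression", "rho_dissim_identity", "rho_behavior")) {
    if (abs(cfg[[nm]]) >= 1)
      .stop_cfg("planted correlation ", nm, " must be strictly inside (-1, 1)")
  }
  if (cfg$noise_sd <= 0) .stop_cfg("noise_sd must be a positive real")
  if (cfg$p_female <= 0 || cfg$p_female >= 1) .stop_cfg("p_female must be in (0, 1)")
  # variance budget: gender loading + brain-behavior loading on the
  # standardized expression score must leave room for residual noise
  b <- .gender_loading(cfg$gender_effect_d, cfg$p_female)
  if (cfg$rho_selectivity_expression^2 + b^2 >= 1)
    .stop_cfg("rho_selectivity_expression and gender_effect_d jointly exceed ",
              "the unit variance budget of the expression score")
  invisible(cfg)
}

# loading of standardized gender on the standardized score that yields a
# within-group Cohen's d of `d` with P(female) = p
.gender_loading <- function(d, p) {
  q <- 1 - p
  d * sqrt(p * q) / sqrt(1 + d^2 * p * q)
}

#' Generate a synthetic cohort with planted brain-behavior effects
#'
#' Draws `n_subjects` subjects. Each subject has a latent amplitude (mean
#' face activation, carried by the per-voxel contrast Z vector) and a latent
#' separation in \[0, 2\] (carried by the angle between the face and object
#' spatial patterns, so that the population between-category dissimilarity
#' equals the latent separation). The expression score is a linear-Gaussian
#' mix of the standardized amplitude (loading
#' `rho_selectivity_expression`), standardized gender, and residual noise;
#' the identity accuracy mixes the standardized separation (loading
#' `rho_dissim_identity`) with noise. Scores are rounded/clipped to their
#' valid ranges and clipping rates are logged in the `clipping` component.
#'
#' Pattern construction: per subject, three orthonormal zero-mean voxel
#' directions u1, u2, u3 are drawn; the object pattern is u1, the face
#' pattern is `cos(theta) u1 + sin(theta) u2` with `cos(theta) = 1 -
#' separation`, and the remaining categories are balanced so the true
#' category-mean pattern is a constant, making the mean-removed face/object
#' correlation exactly `1 - separation` in the noiseless limit. Run-level
#' betas add i.i.d. Gaussian noise with SD `noise_sd`.
#'
#' @param config a [sim_config()].
#' @return an object of class `cohort_sim`: a list with `subjects` (a
#'   data.frame: subject_id, gender, eyes_score, face_acc, flower_acc),
#'   `patterns` (a list of [pattern_matrix()] objects, one per subject),
#'   `truth` (latent per-subject values), `clipping` (clip rates), and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  p <- cfg$p_female

  z_a <- rnorm(n)                      # expression channel (amplitude)
  z_s <- rnorm(n)                      # identity channel (separation)
  gender <- rbinom(n, 1L, p)
  zg <- (gender - p) / sqrt(p * (1 - p))

  amplitude <- cfg$amplitude_mean + cfg$amplitude_sd * z_a
  sep_raw <- cfg$separation_mean + cfg$separation_sd * z_s
  separation <- pmin(pmax(sep_raw, 0), 2)

  b <- .gender_loading(cfg$gender_effect_d, p)
  r_se <- cfg$rho_selectivity_expression
  r_di <- cfg$rho_dissim_identity
  e_expr <- rnorm(n)
  eyes_std <- r_se * z_a + b * zg + sqrt(1 - r_se^2 - b^2) * e_expr

  # optional behavioral cross-correlation, routed through the noise parts so
  # the two neural channels stay independent
  if (cfg$rho_behavior != 0) {
    denom <- sqrt(1 - r_se^2 - b^2) * sqrt(1 - r_di^2)
    rb <- cfg$rho_behavior / denom
    if (abs(rb) >= 1)
      .stop_cfg("rho_behavior too large for the residual variance available")
    e_id <- rb * e_expr + sqrt(1 - rb^2) * rnorm(n)
  } else {
    e_id <- rnorm(n)
  }
  face_std <- r_di * z_s + sqrt(1 - r_di^2) * e_id

  eyes_raw <- cfg$eyes_mean + cfg$eyes_sd * eyes_std
  eyes_score <- pmin(pmax(round(eyes_raw), 0), 36)
  face_raw <- cfg$face_acc_mean + cfg$face_acc_sd * face_std
  face_acc <- pmin(pmax(face_raw, 0), 1)
  flower_raw <- cfg$flower_acc_mean + cfg$flower_acc_sd * rnorm(n)
  flower_acc <- pmin(pmax(flower_raw, 0), 1)

  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    gender = gender,
    eyes_score = as.numeric(eyes_score),
    face_acc = face_acc,
    flower_acc = flower_acc,
    stringsAsFactors = FALSE
  )

  patterns <- vector("list", n)
  for (i in seq_len(n)) {
    patterns[[i]] <- .simulate_patterns(
      amplitude = amplitude[i], separation = separation[i],
      n_voxels = cfg$n_voxels, n_runs = cfg$n_runs,
      categories = cfg$categories, noise_sd = cfg$noise_sd
    )
  }
  names(patterns) <- subjects$subject_id

  truth <- data.frame(
    subject_id = subjects$subject_id,
    amplitude = amplitude, separation = separation,
    gender = gender, z_amplitude = z_a, z_separation = z_s,
    stringsAsFactors = FALSE
  )

  clipping <- c(
    eyes_score = mean(eyes_raw < 0 | eyes_raw > 36),
    face_acc = mean(face_raw < 0 | face_raw > 1),
    flower_acc = mean(flower_raw < 0 | flower_raw > 1),
    separation = mean(sep_raw < 0 | sep_raw > 2)
  )

  structure(list(subjects = subjects, patterns = patterns, truth = truth,
                 clipping = clipping, config = cfg),
            class = "cohort_sim")
}

# true + noisy per-run category patterns for one subject
.simulate_patterns <- function(amplitude, separation, n_voxels, n_runs,
                               categories, noise_sd) {
  nv <- n_voxels
  # three orthonormal zero-mean voxel directions, scaled to unit per-voxel RMS
  M <- matrix(rnorm(nv * 3), nv, 3)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M)) * sqrt(nv)
  u1 <- Q[, 1]; u2 <- Q[, 2]; u3 <- Q[, 3]

  costh <- 1 - separation
  sinth <- sqrt(max(0, 1 - costh^2))
  P_face <- costh * u1 + sinth * u2
  P_obj <- u1

  ncat <- length(categories)
  true_beta <- matrix(0, ncat, nv, dimnames = list(categories, NULL))
  true_beta[1, ] <- amplitude + P_face
  true_beta[2, ] <- P_obj
  if (ncat > 2) {
    m <- ncat - 2
    alt <- rep_len(c(1, -1), m)
    if (m %% 2 == 1) alt[m] <- 0   # keep extras summing to the shared mean
    for (j in seq_len(m)) {
      true_beta[2 + j, ] <- -(P_face + P_obj) / m + alt[j] * u3
    }
  }

  betas <- array(0, dim = c(ncat, n_runs, nv),
                 dimnames = list(categories, NULL, NULL))
  for (cc in seq_len(ncat)) {
    for (r in seq_len(n_runs)) {
      betas[cc, r, ] <- true_beta[cc, ] + rnorm(nv, 0, noise_sd)
    }
  }
  contrast_z <- amplitude + rnorm(nv, 0, noise_sd)

  pattern_matrix(betas, contrast_z)
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects,",
      x$config$n_voxels, "voxels,", x$config$n_runs, "runs,",
      length(x$config$categories), "categories\n")
  cat("Planted effects: rho(selectivity, expression) =",
      x$config$rho_selectivity_expression,
      "; rho(dissimilarity, identity) =", x$config$rho_dissim_identity, "\n")
  cat("Clipping rates:",
      paste(names(x$clipping), signif(x$clipping, 3), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate a block-design BOLD volume for one subject
#'
#' Embeds a spherical "blob" of face-responsive voxels in a small 3-D grid
#' and generates a 4-D time series under the block-design GLM: voxels inside
#' the blob respond to the face condition with the subject's amplitude
#' (other conditions evoke no response), plus i.i.d. Gaussian noise.
#' The ground-truth blob mask is returned for ROI-extraction tests.
#'
#' @param amplitude the subject's face-response amplitude (applied to every
#'   blob voxel).
#' @param design a [design_spec()] whose blocks cover the face condition.
#' @param grid_shape integer 3-vector of grid dimensions (kept small,
#'   e.g. <= 32 per axis).
#' @param seed integer RNG seed.
#' @param noise_sd temporal noise SD added to every voxel's time series.
#' @param blob_center blob center voxel (defaults to the grid center).
#' @param blob_radius blob radius in voxels (Euclidean).
#' @param face_condition label of the face condition in `design`.
#' @return list with `bold` (4-D array x,y,z,time), `mask` (logical 3-D
#'   array, the planted blob), `design` (the design spec), and
#'   `amplitude`.
#' @export
generate_bold <- function(amplitude, design, grid_shape, seed,
                          noise_sd = 1, blob_center = NULL, blob_radius = 2,
                          face_condition = "faces") {
  stopifnot(inherits(design, "design_spec"))
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    .stop_cfg("grid_shape must be a 3-vector of positive integers")
  if (is.null(blob_center)) blob_center <- ceiling(grid_shape / 2)
  if (any(blob_center - blob_radius < 1) || any(blob_center + blob_radius > grid_shape))
    .stop_cfg("grid too small to contain the blob: center ",
              paste(blob_center, collapse = ","), " radius ", blob_radius,
              " exceeds grid ", paste(grid_shape, collapse = "x"))
  if (!face_condition %in% design$blocks$condition)
    .stop_cfg("design has no blocks for the face condition '", face_condition, "'")

  set.seed(as.integer(seed))
  idx <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                               y = seq_len(grid_shape[2]),
                               z = seq_len(grid_shape[3])))
  d2 <- (idx[, 1] - blob_center[1])^2 + (idx[, 2] - blob_center[2])^2 +
    (idx[, 3] - blob_center[3])^2
  mask <- array(d2 <= blob_radius^2, dim = grid_shape)

  X <- build_design(design)
  cond_cols <- attr(X, "condition_columns")
  nvox <- prod(grid_shape)
  nt <- nrow(X)
  signal <- as.numeric(mask) * amplitude      # beta per voxel, face condition
  Y <- tcrossprod(matrix(signal, ncol = 1), X[, cond_cols[[face_condition]], drop = FALSE][, 1])
  if (noise_sd > 0) Y <- Y + matrix(rnorm(nvox * nt, 0, noise_sd), nvox, nt)

  # voxel linear order of Y matches R's array linearization (x fastest)
  list(bold = array(Y, dim = c(grid_shape, nt)),
       mask = mask, design = design, amplitude = amplitude)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `subjects.csv` (subject_id, gender, eyes_score, face_acc,
#' flower_acc) and one `patterns/<subject_id>.csv` per subject with rows =
#' voxels and columns = `<category>_run<r>` betas plus `contrast_z`.
#'
#' @param cohort a `cohort_sim` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_sim"))
  dir.create(file.path(dir, "patterns"), recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (id in names(cohort$patterns)) {
    write_pattern_matrix(cohort$patterns[[id]],
                         file.path(dir, "patterns", paste0(id, ".csv")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `subjects.csv` and `patterns/`.
#' @return a list with `subjects` and `patterns` (named by subject_id).
#' @export
read_cohort <- function(dir) {
  subjects <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  patterns <- lapply(subjects$subject_id, function(id) {
    read_pattern_matrix(file.path(dir, "patterns", paste0(id, ".csv")))
  })
  names(patterns) <- subjects$subject_id
  list(subjects = subjects, patterns = patterns)
}
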