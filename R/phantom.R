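#' Configuration for the synthetic lesion-phantom cohort
#'
#' The generator emulates the structure of a post-intervention acute ischemic
#' stroke cohort: brain-like volumes with a single focal hyperintense lesion,
#' clinical covariates whose marginals mimic a published stroke cohort (age
#' about Normal(62.28, 14.05), admission severity about a truncated
#' Normal(6.21, 6.65) at 0, male prevalence 0.539, a four-level thrombus
#' location with an explicit Missing level), and binary outcomes drawn from a
#' logistic model on standardized lesion volume + covariates, with the
#' intercept calibrated to target prevalences of 0.1891 (length of stay > 8
#' days) and 0.3850 (90-day mRS > 2).
#'
#' @param n_subjects Cohort size (default 200).
#' @param grid_shape Voxels per axis, length 3 (default 32^3).
#' @param voxel_volume mm^3 per voxel (default 8, i.e. 2 mm isotropic).
#' @param lesion_axis_range Min/max lesion semi-axis length in voxels.
#' @param base_intensity Within-brain base intensity. The default 1 emits
#'   volumes on the unit scale of intensity-normalized source data (the
#'   emulated dataset is normalized before publication), so no further
#'   normalization is needed downstream.
#' @param background_noise_sd Gaussian noise SD inside the brain (fraction
#'   of base intensity).
#' @param lesion_contrast Intensity added inside the lesion; 0.6 emulates the
#'   strong diffusion hyperintensity of acute stroke lesions.
#' @param outcome_coefficients Named weights on standardized predictors for
#'   the logistic outcome model (shared by both outcomes).
#' @param target_prevalence Named fractions in (0,1) for `los` and `mrs`.
#' @param missing_rate MCAR missingness fraction for continuous clinical
#'   features (must be < 0.2).
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   config.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_subjects = 200,
                           grid_shape = c(32, 32, 32),
                           voxel_volume = 8,
                           lesion_axis_range = c(2, 6),
                           base_intensity = 1,
                           background_noise_sd = 0.05,
                           lesion_contrast = 0.6,
                           outcome_coefficients = c(lesion_volume = 1.2,
                                                    nihss = 0.7, age = 0.3),
                           target_prevalence = c(los = 0.1891, mrs = 0.3850),
                           missing_rate = 0.05,
                           seed = 1) {
  stopifnot(n_subjects >= 1, length(grid_shape) == 3,
            voxel_volume > 0, all(lesion_axis_range > 0),
            lesion_axis_range[1] <= lesion_axis_range[2],
            background_noise_sd >= 0)
  if (any(grid_shape < 8)) stop("grid_shape must be at least 8 voxels per axis")
  if (any(target_prevalence <= 0 | target_prevalence >= 1))
    stop("target_prevalence must lie strictly in (0,1)")
  if (missing_rate >= 0.2)
    stop("missing_rate must be below 0.2 per feature")
  cfg <- as.list(environment())
  class(cfg) <- "phantom_config"
  cfg
}

#' Generate one brain-like volume
#'
#' The brain mask is a centered ellipsoid covering roughly 38% of the grid
#' (inside the 30-60% band a skull-stripped MNI-space brain occupies); the
#' mask is identical across subjects because the emulated source data is
#' registered to a common template before publication, so anatomy-scale
#' variation has been removed upstream. The image is a constant base
#' intensity inside the mask plus Gaussian noise, and exactly zero outside.
#'
#' @param config A [phantom_config()].
#' @param seed Integer stream seed for this volume.
#' @param subject_id Identifier stored on the sample.
#' @return A `volume_sample`: `image`, `brain_mask`, `lesion_mask` (empty),
#'   `subject_id`, `voxel_volume`.
#' @export
generate_brain_volume <- function(config, seed = config$seed,
                                  subject_id = "s0001") {
  g <- config$grid_shape
  if (any(g < 8)) stop("grid_shape must be at least 8 voxels per axis")
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  semi <- (g / 2) * c(0.92, 0.90, 0.88)   # template anatomy, shared by cohort
  ax <- lapply(1:3, function(a) (seq_len(g[a]) - (g[a] + 1) / 2) / semi[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  brain <- array(as.numeric(d2 <= 1), g)
  noise <- array(rnorm(prod(g), 0, config$background_noise_sd), g)
  image <- (config$base_intensity + noise) * brain
  vol <- list(image = image, brain_mask = brain,
              lesion_mask = array(0, g),
              subject_id = subject_id, voxel_volume = config$voxel_volume)
  class(vol) <- "volume_sample"
  vol
}

ellipsoid_mask <- function(grid_shape, center, semi_axes) {
  ax <- lapply(1:3, function(a)
    ((seq_len(grid_shape[a]) - center[a]) / semi_axes[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  array(as.numeric(d2 <= 1), grid_shape)
}

#' Implant an ellipsoidal lesion into a volume
#'
#' The lesion mask is the voxelized ellipsoid intersected with the brain
#' mask; the image gains `contrast` inside the lesion. The lesion volume in
#' cm^3 (voxel count x voxel volume / 1000) is returned for use as an
#' image-derived feature; it is always computed on the native grid.
#'
#' @param vol A `volume_sample`.
#' @param center Voxel coordinates (1-based, length 3); must lie inside the
#'   brain mask.
#' @param semi_axes Semi-axis lengths in voxels (length 3).
#' @param contrast Intensity added inside the lesion.
#' @return The modified `volume_sample` with `lesion_volume_cm3` attached.
#' @export
implant_lesion <- function(vol, center, semi_axes, contrast) {
  g <- dim(vol$image)
  ci <- round(center)
  if (any(ci < 1) || any(ci > g) ||
      vol$brain_mask[ci[1], ci[2], ci[3]] != 1)
    stop("lesion center lies outside the brain mask")
  les <- ellipsoid_mask(g, center, semi_axes) * vol$brain_mask
  vol$lesion_mask <- les
  vol$image <- vol$image + contrast * les
  vol$lesion_volume_cm3 <- sum(les) * vol$voxel_volume / 1000
  vol
}

#' Calibrate the logistic intercept for a target prevalence
#'
#' Bisection on the intercept until the mean predicted probability over the
#' table is within 1e-4 of the target.
#'
#' @param table data.frame holding the predictor columns.
#' @param coefficients Named numeric weights; names must be columns of
#'   `table`.
#' @param target_prevalence Fraction strictly in (0,1).
#' @param max_iter Bisection iteration cap (default 200).
#' @return The intercept (numeric scalar).
#' @export
calibrate_intercept <- function(table, coefficients, target_prevalence,
                                max_iter = 200) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie strictly in (0,1)")
  lp <- linear_predictor(table, coefficients)
  f <- function(b0) mean(sigmoid(b0 + lp)) - target_prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("intercept calibration failed to bracket")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < 1e-4) return(mid)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  stop("intercept calibration did not converge in ", max_iter, " iterations")
}

linear_predictor <- function(table, coefficients) {
  miss <- setdiff(names(coefficients), names(table))
  if (length(miss))
    stop("unknown predictor(s): ", paste(miss, collapse = ", "))
  lp <- rep(0, nrow(table))
  for (nm in names(coefficients)) {
    x <- table[[nm]]
    if (anyNA(x)) stop("predictor '", nm, "' contains missing values")
    lp <- lp + coefficients[[nm]] * x
  }
  lp
}

#' Draw binary outcomes from a logistic model
#'
#' p_i = logistic(intercept + sum_j coef_j x_ij); labels are Bernoulli(p_i).
#' Probabilities are returned for oracle checks.
#'
#' @inheritParams calibrate_intercept
#' @param intercept Numeric scalar.
#' @param seed Integer seed for the Bernoulli draws.
#' @return List with `labels` (0/1), `probabilities`, `linear_predictor`.
#' @export
generate_outcomes <- function(table, coefficients, intercept, seed = 1) {
  lp <- intercept + linear_predictor(table, coefficients)
  p <- sigmoid(lp)
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  list(labels = rbinom(length(p), 1, p), probabilities = p,
       linear_predictor = lp)
}

zscore <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) s <- 1
  (x - mean(x)) / s
}

#' Generate a full synthetic cohort
#'
#' Per subject: a brain volume, a single ellipsoidal lesion whose size is
#' driven by a latent severity variable (which also drives the NIHSS-like
#' score, giving correlated image and clinical signal), clinical covariates,
#' MCAR missingness on continuous clinical features, and both outcomes. The
#' continuous outcomes (length of stay in days, 90-day mRS) are drawn
#' consistently with the latent binary labels, so dichotomization recovers
#' them exactly.
#'
#' @param config A [phantom_config()].
#' @return A `synthetic_cohort`: `volumes` (list of `volume_sample`),
#'   `table` (data.frame), `truth` (coefficients, intercepts, per-subject
#'   probabilities per outcome).
#' @export
generate_cohort <- function(config) {
  n <- config$n_subjects
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(config$seed)
  ids <- sprintf("s%04d", seq_len(n))
  vol_seeds <- sample.int(.Machine$integer.max, n)
  severity <- rnorm(n)                    # latent stroke severity
  age <- rnorm(n, 62.28, 14.05)
  bmi <- rnorm(n, 29.28, 7.47)
  nihss <- pmax(0, 6.21 + 6.65 * (0.6 * severity + 0.8 * rnorm(n)))
  male <- rbinom(n, 1, 0.539)
  ivtpa <- rbinom(n, 1, 0.671)
  race <- sample(c("Asian", "AfricanAmerican", "Caucasian", NA),
                 n, replace = TRUE, prob = c(0.027, 0.547, 0.343, 0.083))
  thrombus <- sample(c("Bilateral", "Left", "Right", NA),
                     n, replace = TRUE, prob = c(0.1395, 0.3984, 0.3655, 0.0966))
  med_pool <- paste0("med_", 1:16)
  cond_pool <- paste0("cond_", 1:15)
  draw_set <- function(pool, lambda) {
    k <- min(length(pool), rpois(1, lambda))
    if (k == 0) "" else paste(sample(pool, k), collapse = ";")
  }
  medications <- vapply(seq_len(n), function(i) draw_set(med_pool, 3), "")
  conditions <- vapply(seq_len(n), function(i) draw_set(cond_pool, 2), "")

  # lesion size driven by severity: map severity quantile into the semi-axis
  # range, with per-axis jitter
  r <- config$lesion_axis_range
  base_ax <- r[1] + (r[2] - r[1]) * pnorm(severity)
  volumes <- vector("list", n)
  lesion_cm3 <- numeric(n)
  for (i in seq_len(n)) {
    vol <- generate_brain_volume(config, seed = vol_seeds[i], subject_id = ids[i])
    semi <- pmax(0.5, base_ax[i] * runif(3, 0.85, 1.15))
    center <- sample_lesion_center(vol$brain_mask, semi)
    vol <- implant_lesion(vol, center, semi, config$lesion_contrast)
    volumes[[i]] <- vol
    lesion_cm3[i] <- vol$lesion_volume_cm3
  }

  tab <- data.frame(subject_id = ids, age = age, bmi = bmi, nihss = nihss,
                    male = male, ivtpa = ivtpa, race = race,
                    medications = medications, conditions = conditions,
                    lesion_volume = lesion_cm3, thrombus_location = thrombus,
                    stringsAsFactors = FALSE)

  # outcomes on standardized predictors so the coefficients are comparable
  zs <- data.frame(lesion_volume = zscore(lesion_cm3),
                   nihss = zscore(nihss), age = zscore(age))
  coefs <- config$outcome_coefficients
  truth <- list(coefficients = coefs, outcomes = list())
  out_seeds <- sample.int(.Machine$integer.max, 2)
  los_days <- numeric(n); mrs <- integer(n)
  for (k in seq_along(config$target_prevalence)) {
    oc <- names(config$target_prevalence)[k]
    b0 <- calibrate_intercept(zs, coefs, config$target_prevalence[[k]])
    drawn <- generate_outcomes(zs, coefs, b0, seed = out_seeds[k])
    truth$outcomes[[oc]] <- list(intercept = b0,
                                 probabilities = drawn$probabilities,
                                 linear_predictor = drawn$linear_predictor,
                                 labels = drawn$labels)
    if (oc == "los") {
      los_days <- ifelse(drawn$labels == 1,
                         9 + round(rexp(n, 1 / 6)),
                         pmax(1, round(runif(n, 1, 8))))
    } else {
      mrs <- ifelse(drawn$labels == 1, sample(3:6, n, TRUE),
                    sample(0:2, n, TRUE))
    }
  }
  tab$los_days <- los_days
  tab$mrs_90day <- mrs

  # MCAR missingness on continuous clinical features only
  for (nm in c("age", "bmi", "nihss")) {
    drop <- runif(n) < config$missing_rate
    tab[[nm]][drop] <- NA
  }

  cohort <- list(volumes = volumes, table = tab, truth = truth,
                 config = config)
  class(cohort) <- "synthetic_cohort"
  cohort
}

# Uniform draw of a lesion center among brain voxels with enough margin for
# the semi-axes; falls back to any brain voxel if the eroded set is empty.
sample_lesion_center <- function(brain_mask, semi_axes) {
  g <- dim(brain_mask)
  cand <- which(brain_mask == 1)
  coords <- arrayInd(cand, g)
  margin <- ceiling(semi_axes)
  ok <- coords[, 1] > margin[1] & coords[, 1] <= g[1] - margin[1] &
        coords[, 2] > margin[2] & coords[, 2] <= g[2] - margin[2] &
        coords[, 3] > margin[3] & coords[, 3] <= g[3] - margin[3]
  # keep centers whose eroded position is still inside the brain ellipsoid
  inner <- cand[ok]
  if (!length(inner)) inner <- cand
  pick <- inner[sample.int(length(inner), 1)]
  arrayInd(pick, g)[1, ]
}

#' Write a cohort to disk (NIfTI volumes + CSV table + truth JSON)
#'
#' Per subject: `<id>_image.nii.gz`, `<id>_brainmask.nii.gz`,
#' `<id>_lesionmask.nii.gz` with a diagonal affine from the voxel spacing;
#' plus `cohort.csv` and `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spacing <- rep(cohort$config$voxel_volume^(1 / 3), 3)
  for (vol in cohort$volumes) {
    write_volume(vol$image, file.path(dir, paste0(vol$subject_id, "_image.nii.gz")), spacing)
    write_volume(vol$brain_mask, file.path(dir, paste0(vol$subject_id, "_brainmask.nii.gz")), spacing)
    write_volume(vol$lesion_mask, file.path(dir, paste0(vol$subject_id, "_lesionmask.nii.gz")), spacing)
  }
  write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE, na = "")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
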