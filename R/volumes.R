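#' Write a 3-D array as NIfTI-1
#'
#' @param x 3-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm, length 3 (diagonal affine).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = c(1, 1, 1)) {
  img <- array(as.numeric(x), dim(x))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Load a volume and apply its brain mask
#'
#' Reads the image and mask NIfTI files, validates that the mask is binary
#' (values within 1e-6 of {0,1}) and shape-compatible, and returns the
#' voxelwise product, so everything outside the brain is exactly zero.
#'
#' @param image_path,brain_mask_path NIfTI files on a common grid.
#' @param lesion_mask_path Optional lesion mask NIfTI.
#' @param subject_id Identifier (defaults to the image file stem).
#' @return A `volume_sample` with provenance (paths, pixdim) attached.
#' @export
load_volume <- function(image_path, brain_mask_path, lesion_mask_path = NULL,
                        subject_id = NULL) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(brain_mask_path)
  if (!identical(dim(img)[1:3], dim(msk)[1:3]))
    stop("image and brain mask shapes differ")
  check_binary_mask(msk, "brain mask")
  spacing <- RNifti::pixdim(img)[1:3]
  les <- NULL
  if (!is.null(lesion_mask_path)) {
    les <- RNifti::readNifti(lesion_mask_path)
    if (!identical(dim(les)[1:3], dim(img)[1:3]))
      stop("image and lesion mask shapes differ")
    check_binary_mask(les, "lesion mask")
    les <- array(round(as.numeric(les)), dim(img)[1:3])
  }
  vol <- list(image = array(as.numeric(img) * round(as.numeric(msk)), dim(img)[1:3]),
              brain_mask = array(round(as.numeric(msk)), dim(img)[1:3]),
              lesion_mask = les %||% array(0, dim(img)[1:3]),
              subject_id = subject_id %||% sub("(_image)?\\.nii(\\.gz)?$", "",
                                               basename(image_path)),
              voxel_volume = prod(spacing),
              provenance = list(image = image_path, brain_mask = brain_mask_path,
                                lesion_mask = lesion_mask_path,
                                pixdim = spacing))
  class(vol) <- "volume_sample"
  vol
}

check_binary_mask <- function(m, what) {
  v <- as.numeric(m)
  if (any(pmin(abs(v), abs(v - 1)) > 1e-6))
    stop(what, " is not binary")
  invisible(TRUE)
}

#' Resample a volume sample onto a model grid
#'
#' The image is resampled trilinearly, masks with nearest neighbour (so they
#' stay strictly binary), and the image is re-masked afterwards so voxels
#' outside the resampled brain stay exactly zero. The lesion-volume IDF is
#' never recomputed from a resampled mask; it belongs to the native grid.
#'
#' @param vol A `volume_sample`.
#' @param target_shape Integer length-3 grid (>= 8 per axis); upsampling by
#'   more than 8x per axis is rejected.
#' @return The resampled `volume_sample`.
#' @export
resample_to_grid <- function(vol, target_shape) {
  src <- dim(vol$image)
  if (any(target_shape < 8)) stop("target grid must be at least 8 per axis")
  if (any(target_shape / src > 8)) stop("upsampling factor above 8 rejected")
  if (all(target_shape == src)) return(vol)
  brain <- resample_array(vol$brain_mask, target_shape, "nearest")
  vol$image <- resample_array(vol$image, target_shape, "trilinear") * brain
  vol$brain_mask <- brain
  vol$lesion_mask <- resample_array(vol$lesion_mask, target_shape, "nearest")
  vol
}

#' Stack volume samples into a network input batch
#'
#' @param vols List of `volume_sample` on one common grid.
#' @param normalize Per-volume intensity normalization: "none" (default; the
#'   source data is already intensity-normalized), "brain_mean" (divide by
#'   the mean within-brain intensity, putting network inputs on a unit
#'   scale), or "zscore" (center/scale by within-brain mean and SD, then
#'   re-mask).
#' @return A `volume_batch`: array (D,H,W,1,B), `subject_ids`, `grid`.
#' @export
stack_volumes <- function(vols, normalize = c("none", "brain_mean", "zscore")) {
  if (is.logical(normalize)) normalize <- if (normalize) "zscore" else "none"
  normalize <- match.arg(normalize)
  g <- dim(vols[[1]]$image)
  x <- array(0, c(g, 1, length(vols)))
  for (i in seq_along(vols)) {
    v <- vols[[i]]
    if (!identical(dim(v$image), g)) stop("volumes on different grids")
    img <- v$image
    inb <- v$brain_mask == 1
    if (normalize == "brain_mean") {
      mu <- mean(img[inb])
      if (!is.finite(mu) || mu == 0) mu <- 1
      img <- img / mu
    } else if (normalize == "zscore") {
      mu <- mean(img[inb]); s <- stats::sd(img[inb])
      if (!is.finite(s) || s == 0) s <- 1
      img <- (img - mu) / s * v$brain_mask
    }
    x[, , , 1, i] <- img
  }
  structure(list(x = x,
                 subject_ids = vapply(vols, `[[`, "", "subject_id"),
                 grid = g),
            class = "volume_batch")
}
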