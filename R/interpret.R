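#' 3D Grad-CAM saliency volume
#'
#' Channel weights are the spatial mean of the gradient of the logit with
#' respect to the target layer's activations; the heat map is the rectified,
#' weighted channel sum, trilinearly upsampled to the input grid and
#' normalized to a maximum of 1 when nonzero. The target layer defaults to
#' the last residual stage (before any SE block). The
#' autoencoder-embedding classifier has no spatial feature map, so it is not
#' a supported branch.
#'
#' @param model A convolutional `nf_model` (kind "resnet" or "daft").
#' @param volume A `volume_sample`, a (D,H,W) array or a (D,H,W,1,1) array.
#' @param target_layer Layer index or the default last residual stage.
#' @param tab Optional 1 x T conditioning row (DAFT models).
#' @return A `saliency_volume`: `heat` (non-negative, input-grid array),
#'   `target_layer`, `model_hash`.
#' @export
gradcam <- function(model, volume, target_layer = NULL, tab = NULL) {
  if (!model$kind %in% c("resnet", "daft"))
    stop("Grad-CAM needs a CNN branch; the ", model$kind,
         " branch has no spatial feature map at the classifier")
  img <- if (inherits(volume, "volume_sample")) volume$image else volume
  img <- as_vol(img)
  if (length(dim(img)) == 3) dim(img) <- c(dim(img), 1, 1)
  ti <- target_layer %||% model$last_stage_index
  out <- model_forward(model, img, tab = tab, training = FALSE, capture = ti)
  act <- attr(out, "captured")
  dact <- model_backward(model, matrix(1, 1, 1), stop_at = ti)
  w <- gap_fwd(dact)                       # 1 x C spatial-mean gradients
  heat_small <- scale_map(act, w)
  heat_small <- apply(heat_small[, , , , 1, drop = FALSE], 1:3, sum)
  heat_small <- pmax(heat_small, 0)
  heat <- resample_array(array(heat_small, dim(heat_small)[1:3]),
                         dim(img)[1:3], "trilinear")
  heat <- pmax(heat, 0)
  if (max(heat) > 0) heat <- heat / max(heat)
  structure(list(heat = heat, target_layer = ti,
                 model_hash = nf_hash(get_state(model))),
            class = "saliency_volume")
}

#' Fraction of saliency heat inside the lesion
#'
#' sum(heat * lesion_mask) / sum(heat); 0 by convention when the heat map is
#' identically zero. A uniform heat map scores the lesion's share of the
#' volume, so values above that fraction indicate above-chance localization.
#'
#' @param saliency A `saliency_volume` or a non-negative array.
#' @param lesion_mask Binary array on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
localization_score <- function(saliency, lesion_mask) {
  heat <- if (inherits(saliency, "saliency_volume")) saliency$heat else saliency
  if (!identical(dim(heat), dim(lesion_mask)))
    stop("saliency and lesion mask shapes differ")
  tot <- sum(heat)
  if (tot == 0) return(0)
  sum(heat * lesion_mask) / tot
}

#' Write a saliency volume as NIfTI
#'
#' @param saliency A `saliency_volume`.
#' @param path Output path.
#' @param spacing Voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_saliency <- function(saliency, path, spacing = c(1, 1, 1)) {
  write_volume(saliency$heat, path, spacing)
}
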