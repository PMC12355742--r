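# Declarative architecture specs and builders for the three branches of the
# framework: a 3D ResNet-10 (optionally with a squeeze-and-excite layer after
# the last residual stage), a convolutional autoencoder whose bottleneck
# supplies image embeddings, a single-layer classifier head, and a DAFT
# variant of the ResNet that modulates the last feature map with a
# channelwise affine transform conditioned on the tabular features.

#' ResNet-10 specification
#'
#' Basic-block (1,1,1,1) layout: a 7^3 stride-2 stem with batch norm, ReLU
#' and 3^3 max-pool, four stages of one basic residual block each with
#' channel widths (64,128,256,512) and strides (1,2,2,2), global average
#' pooling to a 512-wide feature vector and a single-logit head. Input grids
#' must be at least 16^3 so the spatial dimensions never collapse to zero.
#'
#' @param input_shape Length-3 grid (default 32^3).
#' @param widths Stage channel widths.
#' @param se_enabled Add a squeeze-and-excite layer after the last stage.
#' @param se_reduction SE bottleneck reduction ratio (default 16).
#' @param in_ch Input channels (default 1).
#' @return A `resnet_spec` list.
#' @export
resnet_spec <- function(input_shape = c(32, 32, 32),
                        widths = c(64, 128, 256, 512),
                        se_enabled = FALSE, se_reduction = 16, in_ch = 1) {
  if (any(input_shape < 16))
    stop("ResNet stem requires an input grid of at least 16 per axis")
  structure(list(input_shape = input_shape, widths = widths,
                 se_enabled = se_enabled, se_reduction = se_reduction,
                 in_ch = in_ch),
            class = "resnet_spec")
}

#' Build a randomly initialized ResNet-10
#'
#' Parameter groups are named stem, stage1..stage4, se, head, so freezing is
#' addressable per group.
#'
#' @param spec A [resnet_spec()].
#' @param seed Initialization seed; the same seed gives identical parameters.
#' @return An `nf_model` of kind "resnet".
#' @export
build_resnet <- function(spec, seed = 1) {
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  w <- spec$widths
  layers <- list(
    layer_conv3d(spec$in_ch, w[1], 7, 2, 3, "stem"),
    layer_bn(w[1], "stem"),
    layer_relu("stem"),
    layer_maxpool(3, 2, 1, "stem"),
    layer_resblock(w[1], w[1], 1, "stage1"),
    layer_resblock(w[1], w[2], 2, "stage2"),
    layer_resblock(w[2], w[3], 2, "stage3"),
    layer_resblock(w[3], w[4], 2, "stage4"))
  if (spec$se_enabled)
    layers <- c(layers, list(layer_se(w[4], spec$se_reduction, "se")))
  layers <- c(layers, list(layer_gap("head"),
                           layer_dense(w[4], 1, "head", init_sd = 0.01)))
  m <- nf_model(layers, spec, kind = "resnet")
  m$layers[[1]]$is_input <- TRUE
  m$last_stage_index <- 8L      # output of stage4, before SE
  m
}

#' Convolutional autoencoder specification
#'
#' Encoder: stride-2 3^3 conv blocks (conv + batch norm + ReLU) with the
#' given channel schedule, then a dense bottleneck to an L-dimensional
#' latent vector. Decoder: mirror via nearest-neighbour upsampling followed
#' by 3^3 convolutions, with a linear output layer. Each encoder block
#' halves the grid, so every axis must be divisible by 2^(number of blocks).
#'
#' @param input_shape Length-3 grid (default 32^3).
#' @param channels Encoder channel schedule (default 8, 16, 32).
#' @param latent_dim Embedding width L (default 64).
#' @param in_ch Input channels (default 1).
#' @return An `autoencoder_spec` list.
#' @export
autoencoder_spec <- function(input_shape = c(32, 32, 32),
                             channels = c(8, 16, 32),
                             latent_dim = 64, in_ch = 1) {
  if (latent_dim <= 0) stop("latent_dim must be positive")
  red <- 2^length(channels)
  if (any(input_shape %% red != 0) || any(input_shape / red < 1))
    stop("input grid must be divisible by ", red)
  structure(list(input_shape = input_shape, channels = channels,
                 latent_dim = latent_dim, in_ch = in_ch),
            class = "autoencoder_spec")
}

#' Build a randomly initialized autoencoder
#'
#' Parameter groups: encoder, decoder. The model records how many layers
#' form the encoder so [encode()] can run it alone.
#'
#' @param spec An [autoencoder_spec()].
#' @param seed Initialization seed.
#' @return An `nf_model` of kind "autoencoder".
#' @export
build_autoencoder <- function(spec, seed = 1) {
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  ch <- spec$channels
  nb <- length(ch)
  bott_grid <- spec$input_shape / 2^nb
  bott_w <- prod(bott_grid) * ch[nb]
  enc <- list()
  prev <- spec$in_ch
  for (i in seq_len(nb)) {
    enc <- c(enc, list(layer_conv3d(prev, ch[i], 3, 2, 1, "encoder"),
                       layer_bn(ch[i], "encoder"),
                       layer_relu("encoder")))
    prev <- ch[i]
  }
  enc <- c(enc, list(layer_flatten("encoder"),
                     layer_dense(bott_w, spec$latent_dim, "encoder")))
  dec <- list(layer_dense(spec$latent_dim, bott_w, "decoder"),
              layer_reshape(c(bott_grid, ch[nb]), "decoder"))
  for (i in rev(seq_len(nb))) {
    out_c <- if (i == 1) spec$in_ch else ch[i - 1]
    dec <- c(dec, list(layer_upsample(2, "decoder"),
                       layer_conv3d(ch[i], out_c, 3, 1, 1, "decoder")))
    if (i > 1)
      dec <- c(dec, list(layer_bn(out_c, "decoder"), layer_relu("decoder")))
  }
  m <- nf_model(c(enc, dec), spec, kind = "autoencoder")
  m$layers[[1]]$is_input <- TRUE
  m$encoder_len <- length(enc)
  m
}

#' Single-layer classifier specification
#'
#' One dense layer from the concatenated enabled blocks (image embedding or
#' backbone features, encoded EHR, encoded IDF) to a single logit;
#' probabilities come from the logistic function.
#'
#' @param block_widths Named integer vector of enabled input block widths.
#' @return A `classifier_spec` with `input_width` = sum of block widths.
#' @export
classifier_spec <- function(block_widths) {
  if (!length(block_widths) || any(block_widths <= 0))
    stop("block widths must be positive")
  structure(list(block_widths = block_widths,
                 input_width = sum(block_widths)),
            class = "classifier_spec")
}

#' Build the single-layer classifier
#'
#' @param spec A [classifier_spec()].
#' @param seed Initialization seed.
#' @return An `nf_model` of kind "classifier".
#' @export
build_classifier <- function(spec, seed = 1) {
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  m <- nf_model(list(layer_dense(spec$input_width, 1, "classifier",
                                 init_sd = 0.01)),
                spec, kind = "classifier")
  m
}

#' Build a DAFT-conditioned ResNet
#'
#' The ResNet-10 backbone with a Dynamic Affine Feature Map Transform block
#' between the last residual stage and the pooling head: the pooled feature
#' map concatenated with the tabular vector passes through a small dense
#' bottleneck that emits a per-channel scale alpha and shift beta, applied
#' channelwise. The output layer of the bottleneck is zero-initialized, so
#' the block is the identity at initialization; gradients flow to both the
#' image and tabular paths.
#'
#' @param spec A [resnet_spec()] (se_enabled is ignored; DAFT takes the
#'   conditioning site).
#' @param tab_width Width of the tabular conditioning vector.
#' @param hidden Bottleneck width (default 8).
#' @param seed Initialization seed.
#' @return An `nf_model` of kind "daft".
#' @export
build_daft <- function(spec, tab_width, hidden = 8, seed = 1) {
  m <- build_resnet(resnet_spec(spec$input_shape, spec$widths, FALSE,
                                spec$se_reduction, spec$in_ch), seed)
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed + 1)
  daft <- layer_daft(spec$widths[4], tab_width, hidden, "daft")
  m$layers <- append(m$layers, list(daft), after = m$last_stage_index)
  m$kind <- "daft"
  m$spec$tab_width <- tab_width
  m
}

#' Squeeze-and-excite transform of a feature map
#'
#' s = per-channel global average; w = sigmoid(W2 relu(W1 s + b1) + b2);
#' output channel c is w_c times input channel c.
#'
#' @param feature_map (D,H,W,C,B) array.
#' @param se_params List with W1 (C x h), b1, W2 (h x C), b2.
#' @return Recalibrated feature map, same shape.
#' @export
se_forward <- function(feature_map, se_params) {
  ch <- dim(feature_map)[4]
  if (nrow(se_params$W1) != ch) stop("channel count does not match se_params")
  old <- save_rng(); on.exit(restore_rng(old))
  l <- layer_se(ch, reduction = ch / ncol(se_params$W1))
  l$params <- se_params
  layer_fwd(l, feature_map, training = FALSE)
}

#' DAFT transform of a feature map
#'
#' Channelwise v'_c = alpha_c * v_c + beta_c with (alpha, beta) produced by
#' the conditioning bottleneck from the pooled map and the tabular vector.
#'
#' @param feature_map (D,H,W,C,B) array.
#' @param tabular_vector B x T matrix.
#' @param daft_params List with W1 ((C+T) x h), b1, W2 (h x 2C), b2.
#' @return Transformed feature map, same shape.
#' @export
daft_forward <- function(feature_map, tabular_vector, daft_params) {
  ch <- dim(feature_map)[4]
  tw <- ncol(tabular_vector)
  if (nrow(daft_params$W1) != ch + tw)
    stop("tabular width does not match daft_params")
  old <- save_rng(); on.exit(restore_rng(old))
  l <- layer_daft(ch, tw, hidden = ncol(daft_params$W1))
  l$params <- daft_params
  layer_fwd(l, feature_map, training = FALSE, tab = tabular_vector)
}

#' Image embeddings from a trained encoder
#'
#' Runs the autoencoder's encoder alone, in inference mode, over a volume
#' batch.
#'
#' @param batch A `volume_batch` from [stack_volumes()] (or a raw
#'   (D,H,W,1,B) array).
#' @param model An autoencoder `nf_model`.
#' @return B x L embedding matrix.
#' @export
encode <- function(batch, model) {
  if (model$kind != "autoencoder") stop("encode() needs an autoencoder model")
  x <- if (inherits(batch, "volume_batch")) batch$x else batch
  if (!identical(dim(x)[1:3], as.integer(model$spec$input_shape)) &&
      !identical(as.numeric(dim(x)[1:3]), as.numeric(model$spec$input_shape)))
    stop("volume grid does not match the encoder's input shape")
  for (i in seq_len(model$encoder_len))
    x <- layer_fwd(model$layers[[i]], x, training = FALSE)
  x
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the spec, kind, frozen groups and full learnable
#' state; loading rebuilds the architecture from the spec and restores the
#' state bit-exactly.
#'
#' @param model An `nf_model`.
#' @param path Checkpoint file path.
#' @name checkpoint
#' @export
save_model <- function(model, path) {
  extra <- list()
  if (model$kind == "daft") extra$tab_width <- model$spec$tab_width
  saveRDS(list(kind = model$kind, spec = model$spec, frozen = model$frozen,
               state = get_state(model), extra = extra), path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  m <- switch(ck$kind,
    resnet = build_resnet(ck$spec),
    autoencoder = build_autoencoder(ck$spec),
    classifier = build_classifier(ck$spec),
    daft = build_daft(ck$spec, ck$spec$tab_width),
    stop("unknown checkpoint kind: ", ck$kind))
  set_state(m, ck$state)
  m$frozen <- ck$frozen
  m
}
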