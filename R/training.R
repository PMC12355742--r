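# Experiment harness: clinical / image / combined arms, each with or without
# image-derived features (IDF); transfer-learning / fine-tuning / scratch
# regimes for the ResNet branch; autoencoder pretraining with embedding
# extraction; AUPRC-based checkpoint selection; frozen-backbone classifier
# retraining for the combined arm.

#' Declarative experiment specification
#'
#' Learning-rate defaults follow the regime: classifier-only training uses a
#' constant 0.01; fine-tuning starts at 0.001 with the plateau scheduler;
#' training from scratch starts at 0.1 with the scheduler. Transfer learning
#' implies a frozen backbone.
#'
#' @param arm "clinical", "image" or "combined".
#' @param branch "resnet", "autoencoder" or "daft" (image/combined arms).
#' @param regime "TL", "FT" or "scratch" (resnet branch only).
#' @param use_idf,use_ehr Feature-block switches.
#' @param outcome "los" or "mrs".
#' @param lr Initial learning rate (NULL = regime default).
#' @param scheduler Reduce-on-plateau on validation loss (NULL = regime
#'   default; factor 0.1, patience 5).
#' @param epochs,batch_size Optimization budget.
#' @param seed Integer seed for shuffling and initialization.
#' @param pos_weight Weight positives by n_neg/n_pos in the loss.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(arm = c("clinical", "image", "combined"),
                            branch = NULL, regime = NULL,
                            use_idf = FALSE, use_ehr = TRUE,
                            outcome = c("los", "mrs"),
                            lr = NULL, scheduler = NULL,
                            epochs = 100, batch_size = 64, seed = 1,
                            pos_weight = TRUE) {
  arm <- match.arg(arm)
  outcome <- match.arg(outcome)
  if (arm == "clinical" && !is.null(branch))
    stop("the clinical arm has no image branch")
  if (arm != "clinical" && is.null(branch))
    stop("image/combined arms need a branch")
  if (!is.null(branch))
    branch <- match.arg(branch, c("resnet", "autoencoder", "daft"))
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("TL", "FT", "scratch"))
    if (is.null(branch) || branch != "resnet")
      stop("regimes apply to the resnet branch only")
  }
  classifier_only <- arm == "clinical" || is.null(regime) || regime == "TL"
  if (is.null(lr))
    lr <- if (classifier_only) 0.01 else if (regime == "FT") 0.001 else 0.1
  if (is.null(scheduler)) scheduler <- !classifier_only
  structure(list(arm = arm, branch = branch, regime = regime,
                 use_idf = use_idf, use_ehr = use_ehr, outcome = outcome,
                 lr = lr, scheduler = scheduler, epochs = epochs,
                 batch_size = batch_size, seed = seed,
                 pos_weight = pos_weight),
            class = "experiment_spec")
}

# Validation scores for checkpoint selection. AUPRC is primary; when the
# validation fold happens to contain a single class the threshold-free
# metrics are undefined and selection falls back to (negative) validation
# loss.
val_scores <- function(p, y, pos_weight) {
  loss <- bce_from_probs(p, y, pos_weight)
  if (length(unique(y)) < 2)
    return(list(auprc = NA_real_, auc = NA_real_, loss = loss,
                score = -loss))
  list(auprc = auprc(p, y), auc = auc(p, y), loss = loss,
       score = auprc(p, y))
}

bce_from_probs <- function(p, y, pos_weight = 1) {
  w <- ifelse(y == 1, pos_weight, 1)
  eps <- 1e-12
  -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / sum(w)
}

batch_index <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train the single-layer classifier head
#'
#' Adam on (optionally class-weighted) binary cross-entropy; the checkpoint
#' with the best validation AUPRC is kept and used for any later evaluation.
#' Early stopping monitors validation AUPRC.
#'
#' @param x,y Training feature matrix and 0/1 labels.
#' @param x_val,y_val Validation split (fold-internal, never the hold-out).
#' @param lr Constant learning rate (default 0.01).
#' @param epochs,batch_size,seed Optimization budget and determinism.
#' @param pos_weight Weight positives by n_neg/n_pos.
#' @param patience Early-stopping patience in epochs.
#' @return List: `model` (best checkpoint restored), `record` (per-epoch
#'   losses and validation metrics, best epoch).
#' @export
train_classifier <- function(x, y, x_val, y_val, lr = 0.01, epochs = 100,
                             batch_size = 64, seed = 1, pos_weight = TRUE,
                             patience = 15) {
  if (length(unique(y)) < 2) stop("training fold contains a single class")
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  model <- build_classifier(classifier_spec(c(input = ncol(x))), seed = seed)
  opt <- adam_new()
  pw <- if (pos_weight) sum(y == 0) / sum(y == 1) else 1
  best <- list(score = -Inf, auprc = NA_real_, state = get_state(model),
               epoch = 0L)
  hist <- list()
  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    nb <- 0
    for (bi in batch_index(nrow(x), batch_size)) {
      logit <- model_forward(model, x[bi, , drop = FALSE], training = TRUE)
      ls <- bce_loss(logit, y[bi], pw)
      if (!is.finite(ls$loss)) stop("classifier training diverged (NaN loss)")
      model_backward(model, matrix(ls$dlogit, ncol = 1))
      adam_step(opt, model, lr)
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1
    }
    pv <- as.vector(sigmoid(model_forward(model, x_val)))
    vs <- val_scores(pv, y_val, pw)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                             val_auprc = vs$auprc, val_auc = vs$auc)
    if (vs$score > best$score)
      best <- list(score = vs$score, auprc = vs$auprc,
                   state = get_state(model), epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  set_state(model, best$state)
  list(model = model,
       record = list(history = do.call(rbind, hist), best_epoch = best$epoch,
                     best_val_auprc = best$auprc))
}

#' Train the convolutional autoencoder
#'
#' The volumes are both the input and the reconstruction target (mean squared
#' error). Training aborts with diagnostics if the loss diverges; the encoder
#' of the returned model can be run alone via [encode()].
#'
#' @param x (D,H,W,1,B) array of mask-applied volumes on the model grid, or a
#'   `volume_batch`.
#' @param spec An [autoencoder_spec()] matching the grid.
#' @param epochs,batch_size,lr,seed Optimization budget and determinism.
#' @return List: `model`, `history` (per-epoch training MSE).
#' @export
train_autoencoder <- function(x, spec = NULL, epochs = 30, batch_size = 8,
                              lr = 1e-3, seed = 1) {
  if (inherits(x, "volume_batch")) x <- x$x
  if (is.null(spec)) spec <- autoencoder_spec(input_shape = dim(x)[1:3])
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  model <- build_autoencoder(spec, seed = seed)
  opt <- adam_new()
  n <- dim(x)[5]
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ep_loss <- 0; nb <- 0
    for (bi in batch_index(n, batch_size)) {
      xb <- x[, , , , bi, drop = FALSE]
      out <- model_forward(model, xb, training = TRUE)
      ls <- mse_loss(out, xb)
      if (!is.finite(ls$loss))
        stop("autoencoder training diverged (NaN loss) at epoch ", ep)
      model_backward(model, array(ls$dpred, dim(out)))
      adam_step(opt, model, lr)
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1
    }
    hist[ep] <- ep_loss / nb
  }
  list(model = model, history = hist)
}

#' Self-supervised surrogate backbone
#'
#' When no externally pretrained ResNet-10 checkpoint is supplied, transfer
#' learning and fine-tuning start from this surrogate: the backbone is
#' fitted to regress a pretext target computed from the images themselves
#' (the z-scored mean of the top-5% brightest within-volume voxels, a
#' hyperintensity summary), which requires no outcome labels. It is a
#' surrogate, not a reproduction of any published pretrained weights.
#'
#' @param x (D,H,W,1,B) array of volumes.
#' @param spec A [resnet_spec()].
#' @param epochs,batch_size,lr,seed Optimization budget.
#' @return An `nf_model` of kind "resnet".
#' @export
surrogate_backbone <- function(x, spec, epochs = 4, batch_size = 8,
                               lr = 1e-3, seed = 1) {
  if (inherits(x, "volume_batch")) x <- x$x
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  n <- dim(x)[5]
  tgt <- vapply(seq_len(n), function(i) {
    v <- x[, , , 1, i]
    mean(v[v >= quantile(v, 0.95)])
  }, 0)
  tgt <- zscore(tgt)
  model <- build_resnet(spec, seed = seed)
  opt <- adam_new()
  for (ep in seq_len(epochs)) {
    for (bi in batch_index(n, batch_size)) {
      out <- model_forward(model, x[, , , , bi, drop = FALSE], training = TRUE)
      ls <- mse_loss(as.vector(out), tgt[bi])
      if (!is.finite(ls$loss)) stop("surrogate pretraining diverged")
      model_backward(model, matrix(ls$dpred, ncol = 1))
      adam_step(opt, model, lr)
    }
  }
  model
}

backbone_groups <- c("stem", "stage1", "stage2", "stage3", "stage4", "se")

#' Train a ResNet-10 image classifier under a regime
#'
#' TL: the (pretrained or surrogate) backbone is frozen and only the head
#' trains at the classifier learning rate 0.01. FT: all weights train from
#' the pretrained/surrogate start, initial learning rate 0.001 with the
#' plateau scheduler. scratch: random initialization, initial learning rate
#' 0.1 with the scheduler. The image regimes use plain momentum-free SGD,
#' for which these canonical rates are calibrated; checkpoints are selected
#' by validation AUPRC.
#'
#' @param x,y Training volumes (D,H,W,1,B) and labels.
#' @param x_val,y_val Validation split.
#' @param spec A [resnet_spec()] (set `se_enabled` for the SE variants).
#' @param regime "TL", "FT" or "scratch".
#' @param backbone Optional pretrained `nf_model` whose state seeds TL/FT
#'   (e.g. [surrogate_backbone()] or an imported checkpoint).
#' @param epochs,batch_size,seed,pos_weight,patience As in
#'   [train_classifier()].
#' @param lr,scheduler Overrides of the regime defaults.
#' @return List: `model` (best checkpoint), `record`.
#' @export
train_resnet <- function(x, y, x_val, y_val, spec, regime = c("scratch", "TL", "FT"),
                         backbone = NULL, epochs = 20, batch_size = 8,
                         seed = 1, pos_weight = TRUE, patience = 15,
                         lr = NULL, scheduler = NULL) {
  regime <- match.arg(regime)
  if (inherits(x, "volume_batch")) x <- x$x
  if (inherits(x_val, "volume_batch")) x_val <- x_val$x
  if (length(unique(y)) < 2) stop("training fold contains a single class")
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  model <- build_resnet(spec, seed = seed)
  if (regime %in% c("TL", "FT")) {
    if (is.null(backbone))
      stop("TL/FT need a pretrained or surrogate backbone; see surrogate_backbone()")
    copy_backbone_state(backbone, model)
  }
  if (regime == "TL") freeze_groups(model, intersect(backbone_groups,
                                                     model_groups(model)))
  if (is.null(lr)) lr <- switch(regime, TL = 0.01, FT = 0.001, scratch = 0.1)
  if (is.null(scheduler)) scheduler <- regime != "TL"
  pw <- if (pos_weight) sum(y == 0) / sum(y == 1) else 1
  n <- dim(x)[5]
  best <- list(score = -Inf, auprc = NA_real_, state = get_state(model),
               epoch = 0L)
  hist <- list()
  lr_now <- lr
  plateau <- 0L
  best_vloss <- Inf
  for (ep in seq_len(epochs)) {
    ep_loss <- 0; nb <- 0
    for (bi in batch_index(n, batch_size)) {
      logit <- model_forward(model, x[, , , , bi, drop = FALSE], training = TRUE)
      ls <- bce_loss(logit, y[bi], pw)
      if (!is.finite(ls$loss)) stop("resnet training diverged (NaN loss)")
      model_backward(model, matrix(ls$dlogit, ncol = 1))
      sgd_step(model, lr_now)
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1
    }
    pv <- as.vector(sigmoid(predict_volumes(model, x_val)))
    vs <- val_scores(pv, y_val, pw)
    vls <- vs$loss
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                             val_loss = vls, val_auprc = vs$auprc,
                             val_auc = vs$auc, lr = lr_now)
    if (vs$score > best$score)
      best <- list(score = vs$score, auprc = vs$auprc,
                   state = get_state(model), epoch = ep)
    if (scheduler) {
      if (vls < best_vloss - 1e-6) { best_vloss <- vls; plateau <- 0L }
      else {
        plateau <- plateau + 1L
        if (plateau >= 5L) { lr_now <- lr_now * 0.1; plateau <- 0L }
      }
    }
    if (ep - best$epoch >= patience) break
  }
  set_state(model, best$state)
  list(model = model,
       record = list(history = do.call(rbind, hist), best_epoch = best$epoch,
                     best_val_auprc = best$auprc, regime = regime))
}

model_groups <- function(model)
  unique(vapply(walk_layers(model$layers), function(l) l$group, ""))

# Copy backbone (non-head) parameters and running stats between two ResNets
# of identical topology.
copy_backbone_state <- function(from, to) {
  sf <- walk_layers(from$layers)
  st <- walk_layers(to$layers)
  if (length(sf) != length(st)) stop("backbone topology mismatch")
  for (i in seq_along(sf)) {
    if (sf[[i]]$group == "head") next
    st[[i]]$params <- sf[[i]]$params
    st[[i]]$state <- sf[[i]]$state
  }
  invisible(to)
}

# Batched inference of logits for volume inputs (memory-bounded).
predict_volumes <- function(model, x, tab = NULL, batch_size = 16) {
  n <- dim(x)[5]
  out <- numeric(n)
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    tb <- if (is.null(tab)) NULL else tab[bi, , drop = FALSE]
    out[bi] <- as.vector(model_forward(model, x[, , , , bi, drop = FALSE],
                                       tab = tb))
  }
  out
}

#' Pooled backbone features of a ResNet
#'
#' Runs all layers up to (and including) global average pooling, in
#' inference mode: the 512-wide feature vector the head classifies.
#'
#' @param model A resnet `nf_model`.
#' @param x (D,H,W,1,B) array.
#' @return B x width feature matrix.
#' @export
backbone_features <- function(model, x) {
  if (inherits(x, "volume_batch")) x <- x$x
  n <- length(model$layers)
  out <- NULL
  bsz <- 16
  nb <- dim(x)[5]
  for (bi in split(seq_len(nb), ceiling(seq_len(nb) / bsz))) {
    h <- x[, , , , bi, drop = FALSE]
    for (i in seq_len(n - 1))        # all but the dense head
      h <- layer_fwd(model$layers[[i]], h, training = FALSE)
    out <- rbind(out, h)
  }
  out
}

#' Train the DAFT fusion model end-to-end
#'
#' ResNet backbone with the conditioned affine block; binary cross-entropy;
#' checkpoint selection by validation AUPRC.
#'
#' @param x,tab,y Training volumes, tabular conditioning matrix and labels.
#' @param x_val,tab_val,y_val Validation split.
#' @param spec A [resnet_spec()].
#' @param epochs,batch_size,lr,seed,pos_weight,patience Optimization budget.
#' @return List: `model`, `record`.
#' @export
train_daft <- function(x, tab, y, x_val, tab_val, y_val, spec,
                       epochs = 15, batch_size = 8, lr = 0.001, seed = 1,
                       pos_weight = TRUE, patience = 15) {
  if (inherits(x, "volume_batch")) x <- x$x
  if (inherits(x_val, "volume_batch")) x_val <- x_val$x
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  model <- build_daft(spec, tab_width = ncol(tab), seed = seed)
  pw <- if (pos_weight) sum(y == 0) / sum(y == 1) else 1
  n <- dim(x)[5]
  best <- list(score = -Inf, auprc = NA_real_, state = get_state(model),
               epoch = 0L)
  hist <- list()
  for (ep in seq_len(epochs)) {
    ep_loss <- 0; nb <- 0
    for (bi in batch_index(n, batch_size)) {
      logit <- model_forward(model, x[, , , , bi, drop = FALSE],
                             tab = tab[bi, , drop = FALSE], training = TRUE)
      ls <- bce_loss(logit, y[bi], pw)
      if (!is.finite(ls$loss)) stop("DAFT training diverged (NaN loss)")
      model_backward(model, matrix(ls$dlogit, ncol = 1))
      sgd_step(model, lr)
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1
    }
    pv <- as.vector(sigmoid(predict_volumes(model, x_val, tab = tab_val)))
    vs <- val_scores(pv, y_val, pw)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                             val_auprc = vs$auprc, val_auc = vs$auc)
    if (vs$score > best$score)
      best <- list(score = vs$score, auprc = vs$auprc,
                   state = get_state(model), epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  set_state(model, best$state)
  list(model = model,
       record = list(history = do.call(rbind, hist), best_epoch = best$epoch,
                     best_val_auprc = best$auprc))
}

#' Ridge linear probe from embeddings to a continuous target
#'
#' Measures how much information a latent representation carries about a
#' quantity of interest (e.g. true lesion volume): a ridge-regularized
#' linear readout is fitted on training embeddings and scored as R^2 on
#' held-out embeddings. Ridge (small fixed penalty path, selected by
#' in-train deviance) keeps the probe linear while remaining stable when
#' the embedding width is comparable to n.
#'
#' @param emb_train,y_train Training embeddings (n x L) and targets.
#' @param emb_test,y_test Held-out embeddings and targets.
#' @return List with `r2` (held-out), `lambda`.
#' @export
embedding_probe <- function(emb_train, y_train, emb_test, y_test) {
  foldid <- rep_len(1:5, length(y_train))   # deterministic CV folds
  cv <- glmnet::cv.glmnet(emb_train, y_train, alpha = 0, foldid = foldid,
                          lambda = exp(seq(log(1e3), log(1e-4),
                                           length.out = 80)))
  pr <- as.vector(predict(cv, emb_test, s = "lambda.min"))
  r2 <- 1 - sum((y_test - pr)^2) / sum((y_test - mean(y_train))^2)
  list(r2 = r2, lambda = cv$lambda.min)
}

# Standardize a feature block by train-row statistics (zero-variance-safe).
standardize_block <- function(X, train_idx) {
  mu <- colMeans(X[train_idx, , drop = FALSE])
  s <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  sweep(sweep(X, 2, mu), 2, s, "/")
}

#' Select the best image model across regimes
#'
#' Argmax of mean validation AUPRC across the (identical) folds; ties break
#' to the lower SD, then to the fixed regime order TL, FT, FT+SE, scratch,
#' scratch+SE.
#'
#' @param candidates Named list; each element is a list of per-fold results
#'   with `record$best_val_auprc` (as returned by [train_resnet()]).
#' @return List: `name`, `mean_val_auprc`, `sd_val_auprc`, `candidate`.
#' @export
select_best_image_model <- function(candidates) {
  if (!length(candidates)) stop("no candidates to select from")
  nf <- vapply(candidates, length, 0L)
  if (length(unique(nf)) != 1)
    stop("candidates were not run on identical fold sets")
  order_ref <- c("TL", "FT", "FT+SE", "scratch", "scratch+SE")
  stats <- lapply(candidates, function(cand) {
    v <- vapply(cand, function(r) r$record$best_val_auprc, 0)
    c(mean = mean(v), sd = if (length(v) > 1) sd1(v) else 0)
  })
  mu <- vapply(stats, `[[`, 0, "mean")
  sdv <- vapply(stats, `[[`, 0, "sd")
  rank_pos <- match(names(candidates), order_ref)
  rank_pos[is.na(rank_pos)] <- length(order_ref) + seq_len(sum(is.na(rank_pos)))
  ord <- order(-mu, sdv, rank_pos)
  best <- ord[1]
  list(name = names(candidates)[best], mean_val_auprc = unname(mu[best]),
       sd_val_auprc = unname(sdv[best]), candidate = candidates[[best]])
}
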