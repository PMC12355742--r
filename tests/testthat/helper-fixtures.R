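# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# Small cohort on a 16^3 grid for fast end-to-end tests.
tiny_cohort <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- generate_cohort(phantom_config(
      n_subjects = 40, grid_shape = c(16, 16, 16), voxel_volume = 64,
      lesion_axis_range = c(1.5, 4), seed = 11))
  }
  .fixtures$tiny
}

# Brute-force ROC AUC: count correctly ordered positive-negative pairs.
bruteforce_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force average precision over the exact threshold sweep.
bruteforce_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    rec <- tp / n_pos
    prec <- tp / (tp + fp)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Brute-force voxel-inclusion enumeration of an ellipsoid on a grid.
enumerate_ellipsoid <- function(grid, center, semi) {
  cnt <- 0
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2]))
    for (k in seq_len(grid[3])) {
      if (((i - center[1]) / semi[1])^2 + ((j - center[2]) / semi[2])^2 +
          ((k - center[3]) / semi[3])^2 <= 1) cnt <- cnt + 1
    }
  cnt
}

# ---- shared heavy fixtures for the acceptance checks ----------------------

# Planted-signal experiment: 200-subject 32^3 cohort whose outcome loads on
# lesion volume; clinical arm sees EHR only, combined arm adds the
# autoencoder embedding. Cached per seed; also retains fold-1 embeddings for
# the probe check.
planted_signal <- function(seed) {
  key <- paste0("ps", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  co <- generate_cohort(phantom_config(n_subjects = 200, seed = seed))
  x <- stack_volumes(co$volumes)$x
  y <- dichotomize(co$table$los_days, "los")
  plan <- make_split_plan(y, seed = seed)
  sch <- default_schema()
  auc_clin <- auc_comb <- numeric(3)
  fold1 <- NULL
  for (fi in 1:3) {
    f <- plan$folds[[fi]]
    fit <- train_autoencoder(x[, , , , f$train, drop = FALSE],
                             autoencoder_spec(c(32, 32, 32)),
                             epochs = 5, lr = 2e-3, seed = seed * 100 + fi)
    emb <- neurofuse:::standardize_block(encode(x, fit$model), f$train)
    Xe <- neurofuse:::encode_block(co$table, sch$clinical, f$train)
    rc <- train_classifier(Xe[f$train, ], y[f$train], Xe[f$val, ], y[f$val],
                           seed = seed * 100 + fi)
    pc <- as.vector(plogis(model_forward(rc$model, Xe[plan$test, ])))
    Xc <- cbind(emb, Xe)
    rb <- train_classifier(Xc[f$train, ], y[f$train], Xc[f$val, ], y[f$val],
                           seed = seed * 100 + fi)
    pb <- as.vector(plogis(model_forward(rb$model, Xc[plan$test, ])))
    auc_clin[fi] <- auc(pc, y[plan$test])
    auc_comb[fi] <- auc(pb, y[plan$test])
    if (fi == 1)
      fold1 <- list(emb = emb, train = f$train, test = plan$test,
                    lesion_volume = co$table$lesion_volume)
  }
  res <- list(auc_clinical = auc_clin, auc_combined = auc_comb,
              fold1 = fold1)
  .fixtures[[key]] <- res
  res
}

# Lesion-driven CNN for saliency checks: self-supervised surrogate backbone
# fine-tuned on the outcome, Grad-CAM taken at the second residual stage
# (spatial support survives there on a 32^3 grid). Cached per seed.
gradcam_localization <- function(seed) {
  key <- paste0("gc", seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  co <- generate_cohort(phantom_config(n_subjects = 32, seed = seed))
  x <- stack_volumes(co$volumes)$x
  y <- dichotomize(co$table$mrs_90day, "mrs")
  plan <- make_split_plan(y, seed = seed)
  f <- plan$folds[[1]]
  sur <- surrogate_backbone(x[, , , , f$train, drop = FALSE],
                            resnet_spec(c(32, 32, 32)), epochs = 4,
                            seed = seed)
  fit <- train_resnet(x[, , , , f$train, drop = FALSE], y[f$train],
                      x[, , , , f$val, drop = FALSE], y[f$val],
                      resnet_spec(c(32, 32, 32)), regime = "FT",
                      backbone = sur, epochs = 3, batch_size = 8,
                      seed = seed, patience = 10)
  sc <- ch <- numeric(0)
  for (i in plan$test) {
    sal <- gradcam(fit$model, co$volumes[[i]], target_layer = 6)
    sc <- c(sc, localization_score(sal, co$volumes[[i]]$lesion_mask))
    ch <- c(ch, mean(co$volumes[[i]]$lesion_mask))
  }
  res <- list(score = mean(sc), chance = mean(ch))
  .fixtures[[key]] <- res
  res
}
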