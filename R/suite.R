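# End-to-end experiment suite: mirrors the three-arm design (clinical /
# image / combined, each with and without IDF) over the three shuffle folds
# of one split plan, aggregating test metrics as mean (SD).

#' Suite configuration
#'
#' Controls which arms, branches and regimes run, and the optimization
#' budgets. Defaults are desk-scale (32^3 grids, small epoch counts); all
#' budgets are knobs.
#'
#' @param arms Subset of clinical, image, combined.
#' @param branches Subset of autoencoder, resnet, daft.
#' @param regimes ResNet regimes to compare ("TL", "FT", "scratch"); SE
#'   variants of FT and scratch are added when `se_variants` is TRUE.
#' @param se_variants Also run FT+SE / scratch+SE candidates.
#' @param model_grid Optional target grid for the image branches (volumes
#'   are resampled; IDF stay native).
#' @param latent_dim Autoencoder embedding width.
#' @param ae_epochs,resnet_epochs,daft_epochs,classifier_epochs Epoch budgets.
#' @param ae_lr Autoencoder Adam learning rate.
#' @param ae_batch,image_batch,classifier_batch Batch sizes.
#' @param normalize Per-volume intensity normalization applied when stacking
#'   volumes for the networks (see [stack_volumes()]); "none" by default
#'   because the source volumes (and the phantom) are already
#'   intensity-normalized.
#' @param seed Master seed; all fold/row seeds derive from it.
#' @param threshold Decision threshold for thresholded metrics.
#' @return A `suite_config` list.
#' @export
suite_config <- function(arms = c("clinical", "image", "combined"),
                         branches = c("autoencoder", "resnet", "daft"),
                         regimes = "scratch", se_variants = FALSE,
                         model_grid = NULL, latent_dim = 64,
                         ae_epochs = 12, ae_lr = 2e-3,
                         resnet_epochs = 12, daft_epochs = 10,
                         classifier_epochs = 80,
                         ae_batch = 8, image_batch = 8, classifier_batch = 64,
                         normalize = "none",
                         seed = 1, threshold = 0.5) {
  structure(as.list(environment()), class = "suite_config")
}

encode_block <- function(table, features, train_idx) {
  pp <- fit_preprocessor(table[train_idx, , drop = FALSE], features)
  apply_preprocessor(pp, table)
}

#' Run the full experiment suite on a cohort
#'
#' For every enabled arm x branch x (with/without IDF) cell, trains on each
#' of the three folds and evaluates the selected checkpoint exactly once on
#' the shared hold-out test set, then aggregates metrics as mean (SD). Row
#' structure mirrors a 13-row results table: Clinical (EHR, EHR w/IDF, IDF),
#' Image (Resnet, Resnet w/IDF, AE, AE w/IDF), Combined (DAFT, DAFT w/IDF,
#' Resnet, Resnet w/IDF, AE, AE w/IDF).
#'
#' @param cohort A `synthetic_cohort` (or a list with `table` and `volumes`).
#' @param outcome "los" or "mrs".
#' @param config A [suite_config()].
#' @param plan Optional precomputed [make_split_plan()] plan.
#' @param schema Feature schema (default [default_schema()]).
#' @return A `suite_result`: `table` (aggregated results), `fold_metrics`,
#'   `records`, `plan`, `selected_image_model` (resnet branch), `outcome`.
#' @export
run_suite <- function(cohort, outcome = c("los", "mrs"),
                      config = suite_config(), plan = NULL,
                      schema = default_schema()) {
  outcome <- match.arg(outcome)
  tab <- cohort$table
  ycol <- schema$outcomes[[outcome]]
  labels <- dichotomize(tab[[ycol]], outcome)
  keep <- which(!is.na(labels))
  if (length(keep) < nrow(tab)) {
    tab <- tab[keep, , drop = FALSE]
    cohort$volumes <- cohort$volumes[keep]
    labels <- labels[keep]
  }
  if (is.null(plan)) plan <- make_split_plan(labels, seed = config$seed)
  plan_hash <- nf_hash(unclass(plan))
  te <- plan$test
  need_img <- any(c("image", "combined") %in% config$arms)
  xall <- NULL
  if (need_img) {
    vols <- cohort$volumes
    if (!is.null(config$model_grid))
      vols <- lapply(vols, resample_to_grid, target_shape = config$model_grid)
    xall <- stack_volumes(vols, normalize = config$normalize)$x
  }
  grid <- if (need_img) dim(xall)[1:3] else NULL

  rows <- list()
  add_row <- function(arm, variant, fold_rows, records) {
    rows[[length(rows) + 1]] <<- list(arm = arm, variant = variant,
                                      fold_rows = fold_rows, records = records)
  }
  fold_seed <- function(f, off) config$seed * 1000L + f * 10L + off

  sel_models <- list()
  # per-(row,fold) classifier runner: train on fold-train, select on
  # fold-val, evaluate once on the hold-out
  clf_cell <- function(Xlist, f, off) {
    X <- do.call(cbind, Xlist)
    fold <- plan$folds[[f]]
    res <- train_classifier(X[fold$train, , drop = FALSE], labels[fold$train],
                            X[fold$val, , drop = FALSE], labels[fold$val],
                            lr = 0.01, epochs = config$classifier_epochs,
                            batch_size = config$classifier_batch,
                            seed = fold_seed(f, off))
    pt <- as.vector(sigmoid(model_forward(res$model, X[te, , drop = FALSE])))
    list(test = metric_row(pt, labels[te], config$threshold),
         record = c(res$record,
                    list(fold = f, plan_hash = plan_hash,
                         log_ids = list(train = tab$subject_id[fold$train],
                                        val = tab$subject_id[fold$val]))))
  }
  run_clf_row <- function(arm, variant, Xlist_fun, off) {
    cells <- lapply(seq_along(plan$folds), function(f) clf_cell(Xlist_fun(f), f, off))
    add_row(arm, variant,
            do.call(rbind, lapply(cells, `[[`, "test")),
            lapply(cells, `[[`, "record"))
  }

  # encoded blocks are re-fitted per fold to keep the fit train-only
  ehr_block <- function(f) encode_block(tab, schema$clinical, plan$folds[[f]]$train)
  idf_block <- function(f) encode_block(tab, schema$idf, plan$folds[[f]]$train)

  if ("clinical" %in% config$arms) {
    run_clf_row("Clinical", "EHR", function(f) list(ehr_block(f)), 1L)
    run_clf_row("Clinical", "EHR w/IDF",
                function(f) list(ehr_block(f), idf_block(f)), 2L)
    run_clf_row("Clinical", "IDF", function(f) list(idf_block(f)), 3L)
  }

  # ---- image-branch fold assets ----
  ae_emb <- NULL
  if (need_img && "autoencoder" %in% config$branches) {
    ae_emb <- lapply(seq_along(plan$folds), function(f) {
      fold <- plan$folds[[f]]
      fit <- train_autoencoder(xall[, , , , fold$train, drop = FALSE],
                               autoencoder_spec(grid, latent_dim = config$latent_dim),
                               epochs = config$ae_epochs,
                               batch_size = config$ae_batch,
                               lr = config$ae_lr,
                               seed = fold_seed(f, 4L))
      standardize_block(encode(xall, fit$model), fold$train)
    })
  }
  rn <- NULL
  if (need_img && "resnet" %in% config$branches) {
    spec0 <- resnet_spec(grid)
    cand_names <- config$regimes
    if (config$se_variants)
      cand_names <- c(cand_names,
                      paste0(intersect(config$regimes, c("FT", "scratch")), "+SE"))
    surro <- if (any(c("TL", "FT") %in% config$regimes)) {
      lapply(seq_along(plan$folds), function(f)
        surrogate_backbone(xall[, , , , plan$folds[[f]]$train, drop = FALSE],
                           spec0, seed = fold_seed(f, 5L)))
    }
    candidates <- lapply(setNames(cand_names, cand_names), function(nm) {
      se_on <- grepl("\\+SE$", nm)
      regime <- sub("\\+SE$", "", nm)
      lapply(seq_along(plan$folds), function(f) {
        fold <- plan$folds[[f]]
        train_resnet(xall[, , , , fold$train, drop = FALSE], labels[fold$train],
                     xall[, , , , fold$val, drop = FALSE], labels[fold$val],
                     resnet_spec(grid, se_enabled = se_on),
                     regime = regime,
                     backbone = if (regime %in% c("TL", "FT")) surro[[f]],
                     epochs = config$resnet_epochs,
                     batch_size = config$image_batch,
                     seed = fold_seed(f, 6L))
      })
    })
    sel <- select_best_image_model(candidates)
    sel_models <- sel
    rn <- list(models = lapply(sel$candidate, `[[`, "model"))
    rn$feats <- lapply(seq_along(rn$models), function(f)
      standardize_block(backbone_features(rn$models[[f]], xall),
                        plan$folds[[f]]$train))
  }

  # ---- image arm ----
  if ("image" %in% config$arms) {
    if (!is.null(rn)) {
      fold_rows <- do.call(rbind, lapply(seq_along(plan$folds), function(f) {
        pt <- as.vector(sigmoid(predict_volumes(rn$models[[f]],
                                                xall[, , , , te, drop = FALSE])))
        metric_row(pt, labels[te], config$threshold)
      }))
      add_row("Image", "Resnet", fold_rows,
              lapply(seq_along(sel_models$candidate), function(f)
                c(sel_models$candidate[[f]]$record,
                  list(fold = f, plan_hash = plan_hash))))
      run_clf_row("Image", "Resnet w/IDF",
                  function(f) list(rn$feats[[f]], idf_block(f)), 7L)
    }
    if (!is.null(ae_emb)) {
      run_clf_row("Image", "AE", function(f) list(ae_emb[[f]]), 8L)
      run_clf_row("Image", "AE w/IDF",
                  function(f) list(ae_emb[[f]], idf_block(f)), 9L)
    }
  }

  # ---- combined arm ----
  if ("combined" %in% config$arms) {
    if ("daft" %in% config$branches) {
      for (use_idf in c(FALSE, TRUE)) {
        tabblk <- function(f) {
          blk <- ehr_block(f)
          if (use_idf) blk <- cbind(blk, idf_block(f))
          blk
        }
        cells <- lapply(seq_along(plan$folds), function(f) {
          fold <- plan$folds[[f]]
          Xt <- tabblk(f)
          res <- train_daft(xall[, , , , fold$train, drop = FALSE],
                            Xt[fold$train, , drop = FALSE], labels[fold$train],
                            xall[, , , , fold$val, drop = FALSE],
                            Xt[fold$val, , drop = FALSE], labels[fold$val],
                            resnet_spec(grid),
                            epochs = config$daft_epochs,
                            batch_size = config$image_batch,
                            seed = fold_seed(f, if (use_idf) 11L else 10L))
          pt <- as.vector(sigmoid(predict_volumes(res$model,
                                                  xall[, , , , te, drop = FALSE],
                                                  tab = Xt[te, , drop = FALSE])))
          list(test = metric_row(pt, labels[te], config$threshold),
               record = c(res$record, list(fold = f, plan_hash = plan_hash)))
        })
        add_row("Combined", if (use_idf) "DAFT w/IDF" else "DAFT",
                do.call(rbind, lapply(cells, `[[`, "test")),
                lapply(cells, `[[`, "record"))
      }
    }
    if (!is.null(rn)) {
      run_clf_row("Combined", "Resnet",
                  function(f) list(rn$feats[[f]], ehr_block(f)), 12L)
      run_clf_row("Combined", "Resnet w/IDF",
                  function(f) list(rn$feats[[f]], ehr_block(f), idf_block(f)), 13L)
    }
    if (!is.null(ae_emb)) {
      run_clf_row("Combined", "AE",
                  function(f) list(ae_emb[[f]], ehr_block(f)), 14L)
      run_clf_row("Combined", "AE w/IDF",
                  function(f) list(ae_emb[[f]], ehr_block(f), idf_block(f)), 15L)
    }
  }

  table <- do.call(rbind, lapply(rows, function(r) {
    ag <- aggregate_metrics(r$fold_rows)
    data.frame(arm = r$arm, variant = r$variant,
               auc = ag$mean["auc"], auc_sd = ag$sd["auc"],
               auprc = ag$mean["auprc"], auprc_sd = ag$sd["auprc"],
               recall = ag$mean["recall"], recall_sd = ag$sd["recall"],
               specificity = ag$mean["specificity"],
               specificity_sd = ag$sd["specificity"],
               f1 = ag$mean["f1"], f1_sd = ag$sd["f1"],
               row.names = NULL)
  }))
  structure(list(table = table,
                 fold_metrics = lapply(rows, `[[`, "fold_rows"),
                 records = lapply(rows, `[[`, "records"),
                 plan = plan, plan_hash = plan_hash,
                 test_ids = tab$subject_id[te],
                 selected_image_model = sel_models,
                 outcome = outcome, config = config),
            class = "suite_result")
}

#' Render a suite results table as markdown
#'
#' @param result A `suite_result` (or its `table`).
#' @return Character vector of markdown lines.
#' @export
results_to_markdown <- function(result) {
  tb <- if (inherits(result, "suite_result")) result$table else result
  fmt <- function(m, s) sprintf("%.3f (%.3f)", m, s)
  lines <- c("| Arm | Model | AUC | AUPRC | Recall | Specificity | F1-Score |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tb))) {
    r <- tb[i, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s | %s |",
      r$arm, r$variant, fmt(r$auc, r$auc_sd), fmt(r$auprc, r$auprc_sd),
      fmt(r$recall, r$recall_sd), fmt(r$specificity, r$specificity_sd),
      fmt(r$f1, r$f1_sd)))
  }
  lines
}
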