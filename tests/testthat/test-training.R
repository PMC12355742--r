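test_that("experiment specs enforce arm/branch/regime invariants", {
  expect_error(experiment_spec("clinical", branch = "resnet"), "no image branch")
  expect_error(experiment_spec("image"), "need a branch")
  expect_error(experiment_spec("image", branch = "autoencoder",
                               regime = "FT"), "resnet branch only")
  expect_equal(experiment_spec("clinical")$lr, 0.01)
  expect_false(experiment_spec("clinical")$scheduler)
  ft <- experiment_spec("image", branch = "resnet", regime = "FT")
  expect_equal(ft$lr, 0.001); expect_true(ft$scheduler)
  sc <- experiment_spec("image", branch = "resnet", regime = "scratch")
  expect_equal(sc$lr, 0.1); expect_true(sc$scheduler)
  tl <- experiment_spec("image", branch = "resnet", regime = "TL")
  expect_equal(tl$lr, 0.01)
})

test_that("autoencoder training reduces reconstruction error", {
  co <- tiny_cohort()
  x <- stack_volumes(co$volumes[1:12])$x
  fit <- train_autoencoder(x, autoencoder_spec(c(16, 16, 16), latent_dim = 8),
                           epochs = 4, batch_size = 4, lr = 2e-3, seed = 1)
  expect_lt(fit$history[4], fit$history[1])
  # zero-epoch run equals the seeded initialization
  z <- train_autoencoder(x, autoencoder_spec(c(16, 16, 16), latent_dim = 8),
                         epochs = 0, seed = 7)
  fresh <- build_autoencoder(autoencoder_spec(c(16, 16, 16), latent_dim = 8),
                             seed = 7)
  expect_identical(get_state(z$model), get_state(fresh))
  # degenerate all-zero volumes drive the loss toward zero
  x0 <- array(0, c(16, 16, 16, 1, 6))
  fit0 <- train_autoencoder(x0, autoencoder_spec(c(16, 16, 16), latent_dim = 8),
                            epochs = 6, batch_size = 3, lr = 2e-3, seed = 2)
  expect_lt(tail(fit0$history, 1), 1e-6)
  out0 <- model_forward(fit0$model, x0[, , , , 1:2, drop = FALSE])
  expect_lt(max(abs(out0)), 1e-3)
})

test_that("classifier training saturates on linearly separable features", {
  set.seed(5)
  n <- 80
  X <- cbind(c(rnorm(n / 2, -3), rnorm(n / 2, 3)), matrix(rnorm(n * 3), n))
  y <- rep(c(0, 1), each = n / 2)
  fit <- train_classifier(X, y, X, y, epochs = 40, seed = 1)
  expect_equal(fit$record$best_val_auprc, 1)
  expect_error(train_classifier(X, rep(0, n), X, y), "single class")
})

test_that("classifier selection tracks the best validation epoch", {
  set.seed(6)
  X <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, sigmoid(X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  fit <- train_classifier(X, y, X, y, epochs = 25, seed = 2)
  h <- fit$record$history
  expect_equal(fit$record$best_val_auprc, max(h$val_auprc))
  expect_equal(h$val_auprc[fit$record$best_epoch],
               fit$record$best_val_auprc)
})

test_that("resnet regimes schedule and freeze as declared", {
  co <- tiny_cohort()
  x <- stack_volumes(co$volumes)$x
  y <- dichotomize(co$table$los_days, "los")
  tr <- 1:24; va <- 25:32
  fit <- train_resnet(x[, , , , tr, drop = FALSE], y[tr],
                      x[, , , , va, drop = FALSE], y[va],
                      resnet_spec(c(16, 16, 16)), regime = "scratch",
                      epochs = 3, batch_size = 8, seed = 1, patience = 10)
  h <- fit$record$history
  expect_true(all(diff(h$lr) <= 0))           # scheduler never raises the rate
  expect_equal(nrow(h), 3)
  expect_error(train_resnet(x[, , , , tr, drop = FALSE], y[tr],
                            x[, , , , va, drop = FALSE], y[va],
                            resnet_spec(c(16, 16, 16)), regime = "FT",
                            epochs = 1, seed = 1),
               "backbone")
})

test_that("model selection follows mean AUPRC with documented tie-breaks", {
  mk <- function(vals) lapply(vals, function(v)
    list(record = list(best_val_auprc = v), model = NULL))
  cands <- list(TL = mk(c(0.40, 0.40, 0.40)), FT = mk(c(0.44, 0.44, 0.44)))
  expect_equal(select_best_image_model(cands)$name, "FT")
  one <- list(scratch = mk(0.3))
  expect_equal(select_best_image_model(one)$name, "scratch")
  # equal means: lower SD wins
  tie <- list(FT = mk(c(0.41, 0.44, 0.47)), scratch = mk(c(0.43, 0.44, 0.45)))
  expect_equal(select_best_image_model(tie)$name, "scratch")
  # equal mean and SD: fixed regime order decides
  tie2 <- list(scratch = mk(c(0.4, 0.5)), FT = mk(c(0.4, 0.5)))
  expect_equal(select_best_image_model(tie2)$name, "FT")
  uneven <- list(a = mk(c(0.4, 0.5)), b = mk(0.6))
  expect_error(select_best_image_model(uneven), "identical fold sets")
})

test_that("embedding probe recovers a planted linear signal", {
  set.seed(7)
  X <- matrix(rnorm(150 * 30), 150, 30)
  yv <- X %*% rnorm(30, 0, 0.4) + rnorm(150, 0, 0.4)
  pr <- embedding_probe(X[1:100, ], yv[1:100], X[101:150, ], yv[101:150])
  expect_gt(pr$r2, 0.5)
  noise <- matrix(rnorm(150 * 30), 150, 30)
  pr0 <- embedding_probe(noise[1:100, ], yv[1:100], noise[101:150, ],
                         yv[101:150])
  expect_lt(pr0$r2, 0.2)
})
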