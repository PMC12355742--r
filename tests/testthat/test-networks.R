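test_that("builders are seeded and expose the declared widths", {
  a <- build_resnet(resnet_spec(c(16, 16, 16)), seed = 5)
  b <- build_resnet(resnet_spec(c(16, 16, 16)), seed = 5)
  expect_identical(get_state(a), get_state(b))
  c_ <- build_resnet(resnet_spec(c(16, 16, 16)), seed = 6)
  expect_false(identical(get_state(a), get_state(c_)))

  x <- array(rnorm(16^3 * 2), c(16, 16, 16, 1, 2))
  feats <- backbone_features(a, x)
  expect_equal(dim(feats), c(2, 512))           # head feature width

  expect_equal(classifier_spec(c(emb = 64, ehr = 40, idf = 2))$input_width,
               106)
  expect_error(resnet_spec(c(8, 8, 8)), "at least 16")
  expect_error(autoencoder_spec(c(20, 20, 20)), "divisible")
})

test_that("autoencoder output shape equals its input shape on valid grids", {
  for (g in list(c(16, 16, 16), c(32, 16, 16), c(24, 24, 24))) {
    sp <- autoencoder_spec(g, channels = c(4, 8, 4), latent_dim = 8)
    m <- build_autoencoder(sp, seed = 1)
    x <- array(rnorm(prod(g) * 2), c(g, 1, 2))
    y <- model_forward(m, x)
    expect_equal(dim(y), dim(x))
  }
})

test_that("parameter counting matches closed forms and freezing rules", {
  cl <- build_classifier(classifier_spec(c(all = 106)))
  expect_equal(count_parameters(cl), 107L)      # 106 weights + bias

  l <- neurofuse:::layer_conv3d(1, 8, 3)
  m <- neurofuse:::nf_model(list(l), kind = "generic")
  expect_equal(count_parameters(m), 8L * 27L + 8L)

  rs <- build_resnet(resnet_spec(c(16, 16, 16)))
  expect_error(count_parameters(rs, groups = "nope"), "unknown")
  expect_gt(count_parameters(rs, groups = "head"), 0)
  freeze_groups(rs, neurofuse:::model_groups(rs))
  expect_equal(count_parameters(rs, trainable_only = TRUE), 0L)
})

test_that("squeeze-and-excite honors its gating contract", {
  set.seed(8)
  x <- array(rnorm(4 * 4 * 4 * 2 * 3), c(4, 4, 4, 2, 3))
  mk <- function(b2) list(W1 = matrix(0, 2, 1), b1 = 0,
                          W2 = matrix(0, 1, 2), b2 = b2)
  # unit excitation: identity to 1e-6
  expect_lt(max(abs(se_forward(x, mk(c(40, 40))) - x)), 1e-6)
  # zero excitation: zero map
  expect_lt(max(abs(se_forward(x, mk(c(-40, -40))))), 1e-6)
  # hand-chosen gates (0.5, ~1): channel 1 exactly halved
  y <- se_forward(x, mk(c(0, 40)))
  expect_equal(y[, , , 1, ], x[, , , 1, ] * 0.5, tolerance = 1e-12)
  expect_equal(y[, , , 2, ], x[, , , 2, ], tolerance = 1e-6)
  expect_error(se_forward(x, list(W1 = matrix(0, 5, 1), b1 = 0,
                                  W2 = matrix(0, 1, 5), b2 = rep(0, 5))),
               "channel count")
})

test_that("DAFT is the identity at (alpha, beta) = (1, 0) and at build time", {
  set.seed(9)
  x <- array(rnorm(4 * 4 * 4 * 3 * 2), c(4, 4, 4, 3, 2))
  tabv <- matrix(rnorm(2 * 5), 2, 5)
  id_par <- list(W1 = matrix(0, 8, 4), b1 = rep(0, 4),
                 W2 = matrix(0, 4, 6), b2 = rep(0, 6))
  expect_lt(max(abs(daft_forward(x, tabv, id_par) - x)), 1e-12)

  # single-channel 1x1x1 map: v' = alpha * v + beta = 3 * 2 + 1 = 7
  v <- array(2, c(1, 1, 1, 1, 1))
  par1 <- list(W1 = matrix(0, 2, 1), b1 = 0,
               W2 = matrix(0, 1, 2), b2 = c(2, 1))
  expect_equal(as.numeric(daft_forward(v, matrix(0, 1, 1), par1)), 7)

  # zero-initialized bottleneck output: the built block starts as identity
  dm <- build_daft(resnet_spec(c(16, 16, 16)), tab_width = 4, seed = 2)
  daft_layer <- dm$layers[[dm$last_stage_index + 1]]
  expect_equal(daft_layer$type, "daft")
  h <- array(rnorm(2 * 2 * 2 * 512 * 1), c(2, 2, 2, 512, 1))
  out <- neurofuse:::layer_fwd(daft_layer, h, tab = matrix(rnorm(4), 1, 4))
  expect_lt(max(abs(out - h)), 1e-12)
  expect_error(neurofuse:::layer_fwd(daft_layer, h, tab = matrix(0, 1, 9)),
               "width mismatch")
})

test_that("gradients reach every block, including both DAFT inputs", {
  set.seed(10)
  m <- build_daft(resnet_spec(c(16, 16, 16)), tab_width = 3, seed = 3)
  x <- array(rnorm(16^3 * 2), c(16, 16, 16, 1, 2))
  tabv <- matrix(rnorm(6), 2, 3)
  # the DAFT bottleneck output layer is zero-initialized (identity start),
  # which blocks gradients into its first layer until the first update; take
  # one step, then require gradient everywhere
  for (step in 1:2) {
    out <- model_forward(m, x, tab = tabv, training = TRUE)
    model_backward(m, matrix(c(1, -0.5), 2, 1))
    neurofuse:::sgd_step(m, 1e-3)
  }
  ls <- neurofuse:::walk_layers(m$layers)
  nz <- vapply(ls, function(l) {
    gs <- l$grads
    length(gs) > 0 && any(vapply(gs, function(g) any(g != 0), TRUE))
  }, TRUE)
  expect_gt(mean(nz), 0.95)
  daft_layer <- m$layers[[m$last_stage_index + 1]]
  expect_true(any(daft_layer$grads$W2 != 0))     # image-conditioning path
  expect_true(any(daft_layer$grads$W1 != 0))     # post-step, both layers live
  expect_true(any(daft_layer$dtab != 0))         # tabular path
})

test_that("encoding is deterministic and row-per-volume", {
  m <- build_autoencoder(autoencoder_spec(c(16, 16, 16), latent_dim = 12),
                         seed = 4)
  x1 <- array(rnorm(16^3), c(16, 16, 16, 1, 1))
  x <- array(c(x1, x1, rnorm(16^3)), c(16, 16, 16, 1, 3))
  e <- encode(x, m)
  expect_equal(dim(e), c(3, 12))
  expect_identical(e[1, ], e[2, ])               # identical volumes
  expect_false(identical(e[1, ], e[3, ]))
  expect_error(encode(array(0, c(8, 8, 8, 1, 1)), m), "does not match")
  rs <- build_resnet(resnet_spec(c(16, 16, 16)))
  expect_error(encode(x, rs), "autoencoder")
})

test_that("freezing leaves parameters bit-identical through a training step", {
  set.seed(11)
  x <- array(rnorm(16^3 * 4), c(16, 16, 16, 1, 4))
  y <- c(0, 1, 0, 1)
  sur <- build_resnet(resnet_spec(c(16, 16, 16)), seed = 12)
  before <- vapply(neurofuse:::backbone_groups[1:5], function(g)
    group_hash(sur, g), "")
  fit <- train_resnet(x, y, x, y, resnet_spec(c(16, 16, 16)), regime = "TL",
                      backbone = sur, epochs = 2, batch_size = 2, seed = 1,
                      patience = 5)
  after <- vapply(neurofuse:::backbone_groups[1:5], function(g)
    group_hash(fit$model, g), "")
  expect_identical(before, after)
  expect_false(group_hash(fit$model, "head") ==
               group_hash(build_resnet(resnet_spec(c(16, 16, 16)), seed = 1),
                          "head"))
})

test_that("checkpoints round-trip bit-exactly", {
  m <- build_resnet(resnet_spec(c(16, 16, 16), se_enabled = TRUE), seed = 13)
  freeze_groups(m, "stem")
  p <- tempfile(fileext = ".ckpt")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(get_state(m), get_state(m2))
  expect_identical(m$frozen, m2$frozen)
  x <- array(rnorm(16^3), c(16, 16, 16, 1, 1))
  expect_identical(model_forward(m, x), model_forward(m2, x))
})
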