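test_that("brain volume respects mask, noise and determinism contracts", {
  cfg <- phantom_config(n_subjects = 1, grid_shape = c(16, 16, 16),
                        background_noise_sd = 0, seed = 3)
  v <- generate_brain_volume(cfg, seed = 3)
  inb <- v$brain_mask == 1
  expect_true(all(v$image[inb] == cfg$base_intensity))   # noise-free limit
  expect_true(all(v$image[!inb] == 0))
  frac <- mean(v$brain_mask)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.6)

  cfg2 <- phantom_config(n_subjects = 1, grid_shape = c(16, 16, 16), seed = 9)
  a <- generate_brain_volume(cfg2, seed = 42)
  b <- generate_brain_volume(cfg2, seed = 42)
  expect_identical(a$image, b$image)

  expect_error(phantom_config(grid_shape = c(4, 16, 16)), "at least 8")
})

test_that("implanted lesion voxel count matches brute-force enumeration", {
  cfg <- phantom_config(n_subjects = 1, grid_shape = c(32, 32, 32),
                        voxel_volume = 8, seed = 1)
  v <- generate_brain_volume(cfg, seed = 1)
  v2 <- implant_lesion(v, c(16, 16, 16), c(5, 5, 5), contrast = 0.6)
  n_vox <- sum(v2$lesion_mask)
  expect_equal(n_vox, enumerate_ellipsoid(c(32, 32, 32), c(16, 16, 16),
                                          c(5, 5, 5)))
  # within 10% of the continuous ellipsoid volume (4/3) pi 5^3
  expect_lt(abs(n_vox - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.1)
  expect_equal(v2$lesion_volume_cm3, n_vox * 8 / 1000)

  # sub-voxel ellipsoid contains exactly the center voxel
  v3 <- implant_lesion(v, c(16, 16, 16), c(0.5, 0.5, 0.5), contrast = 1)
  expect_equal(sum(v3$lesion_mask), 1)
  expect_equal(v3$lesion_mask[16, 16, 16], 1)

  # zero contrast leaves intensities unchanged but records the mask
  v4 <- implant_lesion(v, c(16, 16, 16), c(3, 3, 3), contrast = 0)
  expect_identical(v4$image, v$image)
  expect_gt(sum(v4$lesion_mask), 0)

  expect_error(implant_lesion(v, c(1, 1, 1), c(3, 3, 3), 1), "outside")
})

test_that("intercept calibration matches the closed-form logit", {
  tab <- data.frame(xx = rnorm(100))
  b0 <- calibrate_intercept(tab, c(xx = 0), 0.5)
  expect_equal(b0, 0, tolerance = 1e-3)
  b1 <- calibrate_intercept(tab, c(xx = 0), 0.1891)
  expect_equal(b1, log(0.1891 / 0.8109), tolerance = 1e-3)
  # monotone: higher target -> higher intercept
  b2 <- calibrate_intercept(tab, c(xx = 0), 0.3850)
  expect_gt(b2, b1)
  expect_error(calibrate_intercept(tab, c(xx = 0), 1.2), "strictly")
})

test_that("outcome generation follows the logistic link", {
  tab <- data.frame(lesion_volume = rnorm(50))
  out <- generate_outcomes(tab, c(lesion_volume = 0), 0, seed = 1)
  expect_true(all(out$probabilities == 0.5))
  # near-step limit at a steep coefficient
  out2 <- generate_outcomes(tab, c(lesion_volume = 50), 0, seed = 1)
  expect_equal(out2$labels, as.integer(tab$lesion_volume > 0))
  expect_error(generate_outcomes(tab, c(nope = 1), 0), "unknown predictor")
})

test_that("prevalence calibration hits both study targets at n = 2000", {
  for (seed in 1:3) {
    set.seed(seed)
    tab <- data.frame(lesion_volume = rexp(2000), nihss = rnorm(2000),
                      age = rnorm(2000))
    coefs <- c(lesion_volume = 1.2, nihss = 0.7, age = 0.3)
    for (target in c(0.1891, 0.3850)) {
      b0 <- calibrate_intercept(tab, coefs, target)
      out <- generate_outcomes(tab, coefs, b0, seed = seed)
      expect_lt(abs(mean(out$labels) - target), 0.02)
    }
  }
})

test_that("cohort IDF equals voxel count times voxel volume, exactly", {
  co <- tiny_cohort()
  for (i in seq_along(co$volumes)) {
    v <- co$volumes[[i]]
    expect_identical(co$table$lesion_volume[i],
                     sum(v$lesion_mask) * v$voxel_volume / 1000)
    expect_true(all(v$lesion_mask <= v$brain_mask))  # lesion inside brain
    expect_true(all(v$image[v$brain_mask == 0] == 0))
  }
  expect_equal(nrow(co$table), length(co$volumes))
})

test_that("cohort generation is deterministic and outcomes match the truth", {
  cfg <- phantom_config(n_subjects = 8, grid_shape = c(16, 16, 16),
                        lesion_axis_range = c(1.5, 4), seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$volumes[[5]]$image, b$volumes[[5]]$image)
  # the recorded continuous outcomes dichotomize back to the drawn labels
  expect_identical(dichotomize(a$table$los_days, "los"),
                   as.integer(a$truth$outcomes$los$labels))
  expect_identical(dichotomize(a$table$mrs_90day, "mrs"),
                   as.integer(a$truth$outcomes$mrs$labels))
})

test_that("planted coefficient signs are recoverable from the truth", {
  wins <- 0
  for (seed in 1:3) {
    co <- generate_cohort(phantom_config(
      n_subjects = 400, grid_shape = c(16, 16, 16), voxel_volume = 64,
      lesion_axis_range = c(1.5, 4), missing_rate = 0, seed = seed))
    zs <- data.frame(lesion_volume = scale(co$table$lesion_volume)[, 1],
                     nihss = scale(co$table$nihss)[, 1],
                     age = scale(co$table$age)[, 1])
    fit <- glm(co$truth$outcomes$mrs$labels ~ ., data = zs,
               family = binomial())
    signs_ok <- all(sign(coef(fit)[-1]) ==
                    sign(co$truth$coefficients[names(coef(fit)[-1])]))
    wins <- wins + signs_ok
  }
  expect_gte(wins, 2)
})

test_that("written cohorts are byte-identical across runs and readable", {
  cfg <- phantom_config(n_subjects = 3, grid_shape = c(16, 16, 16),
                        lesion_axis_range = c(1.5, 4), seed = 77)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # round-trip through the volume loader is exact
  v <- load_volume(file.path(d1, "s0002_image.nii.gz"),
                   file.path(d1, "s0002_brainmask.nii.gz"),
                   file.path(d1, "s0002_lesionmask.nii.gz"))
  co <- generate_cohort(cfg)
  expect_equal(v$image, co$volumes[[2]]$image)
  expect_equal(v$lesion_mask, co$volumes[[2]]$lesion_mask)
})
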