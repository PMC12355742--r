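test_that("dichotomization uses strict thresholds and reproduces cohort rates", {
  expect_identical(dichotomize(c(8, 9), "los"), c(0L, 1L))
  expect_identical(dichotomize(c(2, 3), "mrs"), c(0L, 1L))
  expect_identical(dichotomize(c(5, NA, 12), "los"), c(0L, NA, 1L))
  expect_error(dichotomize(-1, "los"), "negative")
  expect_error(dichotomize(7, "mrs"), "0..6")

  # cohort arithmetic at the published counts
  los <- c(rep(9, 282), rep(5, 1491 - 282))
  expect_equal(100 * mean(dichotomize(los, "los")), 18.91, tolerance = 0.005)
  mrs <- c(rep(4, 375), rep(1, 974 - 375))
  expect_equal(100 * mean(dichotomize(mrs, "mrs")), 38.50, tolerance = 0.005)
})

test_that("split plans stratify exactly and reproduce deterministically", {
  labels <- rep(c(0, 1), each = 50)
  plan <- make_split_plan(labels, seed = 7)
  expect_length(plan$test, 20)
  expect_equal(sum(labels[plan$test]), 10)       # 10 of each class
  for (f in plan$folds) {
    expect_length(f$val, 16)                     # 20% of the remaining 80
    expect_equal(sum(labels[f$val]), 8)          # class-balanced within 1
    expect_length(intersect(plan$test, c(f$train, f$val)), 0)
    expect_length(intersect(f$train, f$val), 0)
  }
  plan2 <- make_split_plan(labels, seed = 7)
  expect_identical(plan, plan2)
  expect_false(identical(plan, make_split_plan(labels, seed = 8)))
  expect_error(make_split_plan(c(0, 0, 0, 1)), "fewer members|at least")
})

test_that("split plans round-trip through JSON losslessly", {
  labels <- rep(c(0, 1), times = c(30, 12))
  plan <- make_split_plan(labels, seed = 3)
  f <- tempfile(fileext = ".json")
  write_split_plan(plan, f)
  back <- read_split_plan(f)
  expect_equal(back$test, plan$test)
  for (i in 1:3) {
    expect_equal(back$folds[[i]]$train, plan$folds[[i]]$train)
    expect_equal(back$folds[[i]]$val, plan$folds[[i]]$val)
  }
  expect_equal(back$label_hash, plan$label_hash)
})

test_that("preprocessor imputes, scales and encodes from training data only", {
  feats <- list(list(name = "a", type = "continuous"),
                list(name = "g", type = "categorical",
                     levels = c("x", "y", "Missing")),
                list(name = "meds", type = "stringset",
                     levels = c("m1", "m2", "m3")))
  train <- data.frame(a = c(1, 2, NA), g = c("x", "y", NA),
                      meds = c("m1;m3", "", NA), stringsAsFactors = FALSE)
  pp <- fit_preprocessor(train, feats)
  enc <- apply_preprocessor(pp, train)
  expect_equal(ncol(enc), 1 + 3 + 3)
  # imputation with the train mean of the observed values
  test <- data.frame(a = NA, g = "y", meds = "m2")
  enc_te <- apply_preprocessor(pp, test)
  expect_equal(unname(enc_te[1, "a"] * pp$features[[1]]$scale +
                        pp$features[[1]]$center), 1.5)
  # standardized training column: mean 0, population SD 1
  expect_equal(mean(enc[, "a"]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((enc[, "a"] - mean(enc[, "a"]))^2)), 1,
               tolerance = 1e-9)
  # NA categorical goes to the Missing level; empty strings give zero blocks
  expect_equal(unname(enc[3, c("g.x", "g.y", "g.Missing")]), c(0, 0, 1))
  expect_equal(unname(enc[2, c("meds.m1", "meds.m2", "meds.m3")]), c(0, 0, 0))
  expect_equal(unname(enc[3, c("meds.m1", "meds.m2", "meds.m3")]), c(0, 0, 0))
  expect_equal(unname(enc[1, c("meds.m1", "meds.m2", "meds.m3")]), c(1, 0, 1))
  # unseen category encodes as all-zero with a warning
  expect_warning(bad <- apply_preprocessor(pp, data.frame(a = 1, g = "zz",
                                                          meds = "")),
                 "unseen")
  expect_equal(unname(bad[1, c("g.x", "g.y", "g.Missing")]), c(0, 0, 0))
})

test_that("zero-variance continuous features get unit scale with a warning", {
  feats <- list(list(name = "a", type = "continuous"))
  expect_warning(pp <- fit_preprocessor(data.frame(a = c(2, 2, 2)), feats),
                 "zero-variance")
  enc <- apply_preprocessor(pp, data.frame(a = c(2, 3)))
  expect_equal(unname(enc[, 1]), c(0, 1))
})

test_that("default schema encodes 40 clinical and 5 IDF columns", {
  sch <- default_schema()
  co <- tiny_cohort()
  ppc <- fit_preprocessor(co$table, sch$clinical)
  ppi <- fit_preprocessor(co$table, sch$idf)
  expect_equal(ppc$width, 40)
  expect_gte(ppi$width, 2)
  expect_equal(ncol(apply_preprocessor(ppc, co$table)), 40)
  # width is stable across refits on different folds
  pp2 <- fit_preprocessor(co$table[1:20, ], sch$clinical)
  expect_identical(pp2$colnames, ppc$colnames)
})

test_that("applying a train-fitted transform re-centers only the train rows", {
  co <- tiny_cohort()
  sch <- default_schema()
  tr <- 1:25; va <- 26:40
  pp <- fit_preprocessor(co$table[tr, ], sch$clinical)
  enc <- apply_preprocessor(pp, co$table)
  expect_equal(mean(enc[tr, "age"]), 0, tolerance = 1e-9)
  expect_gt(abs(mean(enc[va, "age"])), 1e-6)   # validation is not re-fitted
})

test_that("permutation test attains its extreme p-values", {
  same <- permutation_test(rnorm(20, 0, 1), rnorm(20, 0, 1) * 0 + 0,
                           n_perm = 99, seed = 1)
  ident <- permutation_test(rep(1, 15), rep(1, 15), n_perm = 99, seed = 1)
  expect_equal(ident$p_value, 1)
  sep <- permutation_test(rep(0, 30), rep(10, 30), n_perm = 999, seed = 1)
  expect_equal(sep$p_value, 1 / 1000)
  expect_error(permutation_test(1:3, 2:4, n_perm = 0), "n_perm")
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
  # categorical statistic: disjoint category use is maximally significant
  catp <- permutation_test(factor(rep("a", 25)), factor(rep("b", 25)),
                           n_perm = 199, seed = 2)
  expect_equal(catp$p_value, 1 / 200)
})
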