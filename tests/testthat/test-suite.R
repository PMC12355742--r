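tiny_suite_cfg <- function(...) {
  suite_config(ae_epochs = 1, resnet_epochs = 1, daft_epochs = 1,
               classifier_epochs = 8, seed = 4, ...)
}

test_that("the full suite emits the 13-row arm/variant table", {
  co <- tiny_cohort()
  res <- run_suite(co, outcome = "mrs", config = tiny_suite_cfg())
  expect_equal(nrow(res$table), 13)
  expect_equal(res$table$variant,
               c("EHR", "EHR w/IDF", "IDF",
                 "Resnet", "Resnet w/IDF", "AE", "AE w/IDF",
                 "DAFT", "DAFT w/IDF", "Resnet", "Resnet w/IDF",
                 "AE", "AE w/IDF"))
  expect_equal(unique(res$table$arm), c("Clinical", "Image", "Combined"))
  expect_true(all(res$table$auc >= 0 & res$table$auc <= 1))
  expect_true(all(res$table$auprc >= 0 & res$table$auprc <= 1))
  md <- results_to_markdown(res)
  expect_length(md, 15)                       # header + rule + 13 rows

  # every classifier record carries the one plan hash; the hold-out ids
  # never appear in any training/validation log
  for (row in res$records) for (rec in row) {
    expect_equal(rec$plan_hash, res$plan_hash)
    if (!is.null(rec$log_ids))
      expect_length(intersect(res$test_ids, unlist(rec$log_ids)), 0)
  }
})

test_that("disabling arms or branches drops the matching rows", {
  co <- tiny_cohort()
  res <- run_suite(co, outcome = "mrs",
                   config = tiny_suite_cfg(arms = "clinical"))
  expect_equal(res$table$arm, rep("Clinical", 3))
  res2 <- run_suite(co, outcome = "mrs",
                    config = tiny_suite_cfg(arms = c("clinical", "combined"),
                                            branches = "autoencoder"))
  expect_equal(res2$table$variant, c("EHR", "EHR w/IDF", "IDF", "AE", "AE w/IDF"))
})

test_that("suite reruns with the same seed are identical", {
  co <- tiny_cohort()
  cfg <- tiny_suite_cfg(arms = c("clinical", "combined"),
                        branches = "autoencoder")
  r1 <- run_suite(co, outcome = "mrs", config = cfg)
  r2 <- run_suite(co, outcome = "mrs", config = cfg)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$plan_hash, r2$plan_hash)
})

test_that("subjects missing an outcome leave that outcome's cohort", {
  co <- tiny_cohort()
  co$table$mrs_90day[c(2, 9)] <- NA
  res <- run_suite(co, outcome = "mrs",
                   config = tiny_suite_cfg(arms = "clinical"))
  n_eval <- res$fold_metrics[[1]]$n_pos[1] + res$fold_metrics[[1]]$n_neg[1]
  expect_equal(length(res$plan$test), n_eval)
  # the 38 remaining subjects bound every index in the plan
  expect_lte(max(unlist(lapply(res$plan$folds, unlist)), res$plan$test), 38)
  expect_false(any(c("s0002", "s0009") %in% res$test_ids))
})

test_that("the command-line front end runs phantom, split and report", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "neurofuse.R", package = "neurofuse")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out1 <- file.path(tempdir(), "cli_phantom")
  unlink(out1, recursive = TRUE)
  st <- system2(rscript, c(cli, "phantom", "--out", out1, "--n", "20",
                           "--seed", "5"), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out1, "cohort.csv")))
  expect_true(file.exists(file.path(out1, "truth.json")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_length(list.files(out1, pattern = "_image\\.nii\\.gz$"), 20)

  # rerun without --force fails on the non-empty directory
  st2 <- suppressWarnings(
    system2(rscript, c(cli, "phantom", "--out", out1, "--n", "20",
                       "--seed", "5"), stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(st2, "status")))

  plan_file <- file.path(tempdir(), "cli_plan.json")
  system2(rscript, c(cli, "split", "--cohort",
                     file.path(out1, "cohort.csv"), "--outcome", "mrs",
                     "--seed", "5", "--out", plan_file),
          stdout = TRUE, stderr = TRUE)
  plan <- read_split_plan(plan_file)
  expect_length(plan$folds, 3)

  # evaluate before train reports the missing artifact
  st3 <- suppressWarnings(
    system2(rscript, c(cli, "evaluate", "--run", tempdir(), "--out",
                       file.path(tempdir(), "r.csv")),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(st3, "status")))
})
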