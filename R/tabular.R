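#' Default feature schema for the stroke cohort
#'
#' Declares the tabular features in three kinds: continuous (mean-imputed,
#' standardized), binary (0/1, absent treated as false), and categorical
#' (one-hot over declared levels; a declared "Missing" level absorbs NA).
#' Medication and condition history arrive as semicolon-separated strings and
#' become fixed indicator blocks that are all-zero when the string is absent.
#' The default clinical block encodes to exactly 40 columns; the image-derived
#' features (IDF) are lesion volume (cm^3) and thrombus location with an
#' explicit Missing level.
#'
#' @param n_meds,n_conds Sizes of the medication / condition indicator blocks.
#' @return A `nf_schema` list with `clinical`, `idf`, `outcomes`.
#' @export
default_schema <- function(n_meds = 16, n_conds = 15) {
  clinical <- list(
    list(name = "age", type = "continuous"),
    list(name = "bmi", type = "continuous"),
    list(name = "nihss", type = "continuous"),
    list(name = "male", type = "binary"),
    list(name = "ivtpa", type = "binary"),
    list(name = "race", type = "categorical",
         levels = c("Asian", "AfricanAmerican", "Caucasian", "Missing")),
    list(name = "medications", type = "stringset",
         levels = paste0("med_", seq_len(n_meds))),
    list(name = "conditions", type = "stringset",
         levels = paste0("cond_", seq_len(n_conds)))
  )
  idf <- list(
    list(name = "lesion_volume", type = "continuous"),
    list(name = "thrombus_location", type = "categorical",
         levels = c("Bilateral", "Left", "Right", "Missing"))
  )
  schema <- list(clinical = clinical, idf = idf,
                 outcomes = list(los = "los_days", mrs = "mrs_90day"))
  class(schema) <- "nf_schema"
  nm <- unlist(lapply(c(clinical, idf), `[[`, "name"))
  if (anyDuplicated(nm)) stop("feature names must be unique")
  schema
}

encoded_width <- function(features) {
  sum(vapply(features, function(f) switch(f$type,
    continuous = 1L, binary = 1L,
    categorical = length(f$levels), stringset = length(f$levels)), 1L))
}

#' Dichotomize a continuous outcome
#'
#' Poor outcome (positive class) is strictly greater than the threshold:
#' length of stay > 8 days, 90-day mRS > 2. Boundary values are negative;
#' missing outcomes stay missing (those subjects drop out of that outcome's
#' cohort).
#'
#' @param values Numeric vector (NA allowed).
#' @param outcome "los" or "mrs".
#' @return Integer 0/1 vector with NA preserved.
#' @export
dichotomize <- function(values, outcome = c("los", "mrs")) {
  outcome <- match.arg(outcome)
  ok <- !is.na(values)
  if (outcome == "los") {
    if (any(values[ok] < 0)) stop("negative length of stay")
    thr <- 8
  } else {
    if (any(values[ok] < 0 | values[ok] > 6)) stop("mRS must lie in 0..6")
    thr <- 2
  }
  ifelse(is.na(values), NA_integer_, as.integer(values > thr))
}

# Stratified sample of round(frac * n_c) indices per class.
strat_sample <- function(idx, labels, frac) {
  unlist(lapply(unique(labels), function(cl) {
    pool <- idx[labels == cl]
    sample(pool, round(frac * length(pool)))
  }), use.names = FALSE)
}

#' Build the hold-out / three-fold split plan
#'
#' One stratified 20% hold-out test set, then three stratified shuffle folds
#' over the remainder, each with 80% training and 20% validation. Shuffle
#' folds may share training subjects across folds (they are independent
#' stratified draws, not a partition); the test set is identical across folds
#' and untouched by any fit. Class proportions in every part are within one
#' subject of the cohort proportion.
#'
#' @param labels 0/1 vector for the outcome's cohort (no NA).
#' @param test_fraction,n_folds,fold_val_fraction Split geometry.
#' @param seed Integer; the plan is a pure function of labels and seed.
#' @return An `nf_split_plan` list: `test`, `folds` (list of
#'   `list(train, val)`), `seed`, `label_hash`.
#' @export
make_split_plan <- function(labels, test_fraction = 0.2, n_folds = 3,
                            fold_val_fraction = 0.2, seed = 1) {
  if (any(is.na(labels))) stop("labels must be complete for this cohort")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("need at least 2 subjects per class")
  if (any(tab < n_folds))
    stop("a class has fewer members than folds; cannot stratify")
  idx <- seq_along(labels)
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(seed)
  test <- sort(strat_sample(idx, labels, test_fraction))
  rest <- setdiff(idx, test)
  folds <- lapply(seq_len(n_folds), function(f) {
    val <- sort(strat_sample(rest, labels[rest], fold_val_fraction))
    list(train = setdiff(rest, val), val = val)
  })
  plan <- list(test = test, folds = folds, seed = seed,
               n_folds = n_folds, test_fraction = test_fraction,
               fold_val_fraction = fold_val_fraction,
               label_hash = nf_hash(as.integer(labels)))
  class(plan) <- "nf_split_plan"
  plan
}

save_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Serialize / read a split plan as JSON
#'
#' @param plan An `nf_split_plan`.
#' @param path File path.
#' @name split_plan_io
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname split_plan_io
#' @export
read_split_plan <- function(path) {
  plan <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan$test <- as.integer(plan$test)
  if (is.data.frame(plan$folds))
    plan$folds <- lapply(seq_len(nrow(plan$folds)), function(i)
      list(train = as.integer(plan$folds$train[[i]]),
           val = as.integer(plan$folds$val[[i]])))
  else
    plan$folds <- lapply(plan$folds, function(f)
      list(train = as.integer(f$train), val = as.integer(f$val)))
  class(plan) <- "nf_split_plan"
  plan
}

#' Fit the tabular preprocessing pipeline on training rows only
#'
#' Continuous: missing values imputed with the training mean, then
#' standardized by training mean and (population) SD; a zero-variance column
#' gets SD 1 with a warning. Binary: NA treated as 0 (absent means false).
#' Categorical: one-hot over the schema's declared levels; NA maps to a
#' declared "Missing" level if present, otherwise to an all-zero row; a level
#' unseen in the schema encodes as all-zero with a warning at apply time.
#' String-set features (medication/condition strings, semicolon-separated)
#' become fixed indicator blocks, all-zero when the string is empty or NA.
#'
#' @param train_df data.frame of raw training rows.
#' @param features List of schema feature descriptors (e.g.
#'   `schema$clinical`, or `c(schema$clinical, schema$idf)`).
#' @return An `nf_preprocessor`; apply with [apply_preprocessor()].
#' @export
fit_preprocessor <- function(train_df, features) {
  fitted <- lapply(features, function(f) {
    x <- train_df[[f$name]]
    if (is.null(x)) stop("feature absent from table: ", f$name)
    if (f$type == "continuous") {
      mu <- mean(x, na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      xi <- ifelse(is.na(x), mu, x)
      s <- sqrt(mean((xi - mean(xi))^2))
      if (s == 0) {
        warning("zero-variance continuous feature '", f$name, "': SD set to 1")
        s <- 1
      }
      c(f, list(impute = mu, center = mean(xi), scale = s))
    } else f
  })
  pp <- list(features = fitted, width = encoded_width(features),
             colnames = unlist(lapply(fitted, feature_colnames)))
  class(pp) <- "nf_preprocessor"
  pp
}

feature_colnames <- function(f) {
  switch(f$type,
         continuous = f$name, binary = f$name,
         categorical = paste(f$name, f$levels, sep = "."),
         stringset = paste(f$name, f$levels, sep = "."))
}

#' Apply a fitted preprocessor to any rows
#'
#' Stateless after fit: the same input always yields the same encoded matrix.
#'
#' @param pp An `nf_preprocessor` from [fit_preprocessor()].
#' @param df data.frame with the schema's raw columns.
#' @return Numeric matrix, `nrow(df)` x `pp$width`, with column names.
#' @export
apply_preprocessor <- function(pp, df) {
  blocks <- lapply(pp$features, function(f) {
    x <- df[[f$name]]
    if (is.null(x)) stop("feature absent from table: ", f$name)
    switch(f$type,
      continuous = {
        xi <- ifelse(is.na(x), f$impute, x)
        matrix((xi - f$center) / f$scale, ncol = 1)
      },
      binary = matrix(as.numeric(ifelse(is.na(x), 0, x)), ncol = 1),
      categorical = {
        x <- as.character(x)
        if ("Missing" %in% f$levels) x[is.na(x)] <- "Missing"
        unseen <- stats::na.omit(setdiff(unique(x), f$levels))
        if (length(unseen))
          warning("unseen level(s) in '", f$name, "': ",
                  paste(unseen, collapse = ", "), " encoded as all-zero")
        m <- matrix(0, length(x), length(f$levels))
        for (j in seq_along(f$levels)) m[, j] <- as.numeric(!is.na(x) & x == f$levels[j])
        m
      },
      stringset = {
        x <- as.character(x)
        m <- matrix(0, length(x), length(f$levels))
        toks <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
        for (i in seq_along(toks)) {
          hit <- match(trimws(toks[[i]]), f$levels)
          hit <- hit[!is.na(hit)]
          m[i, hit] <- 1
        }
        m
      })
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- pp$colnames
  out
}

#' Two-sided permutation test for a group difference
#'
#' Statistic: absolute mean difference for continuous data, or a chi-square
#' distance between category proportions for categorical data. The p-value
#' uses the add-one estimator (1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1),
#' so the smallest attainable p is 1/(n_perm + 1).
#'
#' @param a,b Vectors for the two groups (numeric, or factor/character).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `p_value`, `statistic`, `n_perm`.
#' @export
permutation_test <- function(a, b, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  categorical <- is.factor(a) || is.character(a)
  pooled <- c(a, b)
  na <- length(a)
  stat <- if (categorical) {
    lev <- sort(unique(as.character(pooled)))
    function(x, y) {
      pa <- tabulate(match(as.character(x), lev), length(lev)) / length(x)
      pb <- tabulate(match(as.character(y), lev), length(lev)) / length(y)
      pe <- (pa * length(x) + pb * length(y)) / (length(x) + length(y))
      keep <- pe > 0
      sum((pa - pb)[keep]^2 / pe[keep])
    }
  } else function(x, y) abs(mean(x) - mean(y))
  obs <- stat(a, b)
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(seed)
  hits <- 0L
  n <- length(pooled)
  for (i in seq_len(n_perm)) {
    pidx <- sample.int(n, na)
    if (stat(pooled[pidx], pooled[-pidx]) >= obs) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (n_perm + 1), statistic = obs, n_perm = n_perm)
}
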