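# A compact synthetic "cohort" for classifier-level tests: summaries and
# frequency features drawn directly at the feature level (fast), with a
# group shift on a handful of bins.
fake_cohort_features <- function(n_pd = 20, n_control = 15, shift = 1,
                                 seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("pd%02d", 1:n_pd), sprintf("hc%02d", 1:n_control))
  groups <- rep(c("PD", "control"), c(n_pd, n_control))
  summ <- data.frame(subject_id = ids, group = groups,
                     stringsAsFactors = FALSE)
  for (p in saccade_parameter_names())
    summ[[p]] <- rnorm(length(ids), mean = 100, sd = 10) +
      ifelse(groups == "PD", shift * 5, 0)
  grid <- expand.grid(eye = c("left", "right"), frequency_hz = spectrum_freqs(),
                      stringsAsFactors = FALSE)
  feats <- list()
  for (i in seq_along(ids)) for (task in task_types()) {
    amp <- abs(rnorm(nrow(grid), 0.1, 0.02))
    hot <- grid$frequency_hz %in% c(2.1, 11.8, 17.4)
    if (groups[i] == "PD") amp[hot] <- amp[hot] + shift * 0.2
    feats[[paste(ids[i], task)]] <- data.frame(
      subject_id = ids[i], group = groups[i], task = task,
      eye = grid$eye, frequency_hz = grid$frequency_hz, amplitude = amp,
      band = assign_band(grid$frequency_hz), stringsAsFactors = FALSE)
  }
  list(summaries = summ, features = do.call(rbind, feats))
}

test_that("feature matrices have the documented shapes per set", {
  fc <- fake_cohort_features()
  dims <- c(basic = 14, freq_pro = 382, freq_anti = 382,
            `freq_pro+basic` = 396, `freq_anti+basic` = 396, all = 778)
  for (s in feature_sets()) {
    fm <- build_feature_matrix(fc$summaries, fc$features, s)
    expect_equal(ncol(fm$x), unname(dims[s]), info = s)
    expect_equal(nrow(fm$x), 35L)
    expect_false(anyNA(fm$y))
  }
})

test_that("select_features keeps exactly the flagged columns", {
  fc <- fake_cohort_features()
  fm <- build_feature_matrix(fc$summaries, fc$features, "basic")
  res <- data.frame(feature_id = colnames(fm$x),
                    p_value = seq(0.001, 0.9, length.out = 14),
                    significant = FALSE, stringsAsFactors = FALSE)
  res$significant[c(2, 5, 9)] <- TRUE
  red <- select_features(res, fm)
  expect_identical(colnames(red$x), colnames(fm$x)[c(2, 5, 9)])
  # all significant -> identity
  res$significant <- TRUE
  expect_identical(colnames(select_features(res, fm)$x), colnames(fm$x))
  # none significant -> top-5 fallback by p-value
  res$significant <- FALSE
  red5 <- select_features(res, fm)
  expect_identical(colnames(red5$x), colnames(fm$x)[1:5])
})

test_that("evaluate is deterministic and near-perfect on separated groups", {
  fc <- fake_cohort_features(shift = 4)
  fm <- build_feature_matrix(fc$summaries, fc$features, "freq_pro")
  r1 <- evaluate(fm, folds = 5, repeats = 2, seed = 11, ntree = 100)
  r2 <- evaluate(fm, folds = 5, repeats = 2, seed = 11, ntree = 100)
  expect_identical(r1[c("accuracy", "precision", "recall", "f1")],
                   r2[c("accuracy", "precision", "recall", "f1")])
  expect_gte(r1$accuracy, 0.95)
  expect_true(all(unlist(r1[c("accuracy", "precision", "recall", "f1")]) <= 1))
})

test_that("permuted labels drive accuracy to chance", {
  fc <- fake_cohort_features(n_pd = 34, n_control = 34, shift = 2, seed = 9)
  fm <- build_feature_matrix(fc$summaries, fc$features, "all")
  set.seed(21)
  fm$y <- sample(fm$y)
  r <- evaluate(fm, folds = 5, repeats = 2, seed = 4, ntree = 150)
  expect_gt(r$accuracy, 0.35)
  expect_lt(r$accuracy, 0.65)
})

test_that("reported metrics equal recomputation from stored predictions", {
  fc <- fake_cohort_features(shift = 1.5)
  fm <- build_feature_matrix(fc$summaries, fc$features, "basic")
  r <- evaluate(fm, folds = 4, repeats = 3, seed = 2, ntree = 80)
  per_rep <- lapply(split(r$predictions, r$predictions$repeat_), function(d)
    unlist(classification_metrics(factor(d$truth, levels = levels(fm$y)),
                                  factor(d$predicted, levels = levels(fm$y)))))
  agg <- colMeans(do.call(rbind, per_rep))
  expect_equal(r$accuracy, unname(agg["accuracy"]), tolerance = 1e-12)
  expect_equal(r$f1, unname(agg["f1"]), tolerance = 1e-12)
})

test_that("evaluate rejects degenerate inputs", {
  fc <- fake_cohort_features(n_pd = 6, n_control = 6)
  fm <- build_feature_matrix(fc$summaries, fc$features, "basic")
  fm$y <- factor(rep("PD", 12), levels = c("control", "PD"))
  expect_error(evaluate(fm), "class")
})
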