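# Diagnostic classification: feature-matrix assembly over the six feature-set
# configurations, significance-based feature selection, and repeated
# stratified cross-validated random-forest evaluation.

#' The six feature-set configurations
#' @return Character vector of feature-set tags.
#' @export
feature_sets <- function() c("basic", "freq_pro", "freq_anti",
                             "freq_pro+basic", "freq_anti+basic", "all")

freq_col_name <- function(task, eye, f) {
  short <- ifelse(task == "pro_saccade", "pro", "anti")
  sprintf("%s_%s_f%04.1f", short, eye, f)
}

#' Assemble a subject x feature matrix
#'
#' Columns depend on the feature-set tag: the 14 basic saccadic parameters,
#' the 382 pro-saccade frequency features (191 bins x 2 eyes), the 382
#' anti-saccade frequency features, their unions, or all 778.
#'
#' @param summaries Subject saccadic summaries (rows with `subject_id`,
#'   `group`, the 14 parameters).
#' @param features Stacked frequency features from [subject_features()].
#' @param set Feature-set tag; see [feature_sets()].
#' @return A `feature_matrix`: list with `x` (numeric matrix), `y` (factor
#'   `control`/`PD`), `subject_id`, and `set`.
#' @export
build_feature_matrix <- function(summaries, features, set = "all") {
  set <- match.arg(set, feature_sets())
  ids <- summaries$subject_id
  y <- factor(summaries$group, levels = c("control", "PD"))
  if (anyNA(y)) stop("missing group labels", call. = FALSE)
  blocks <- list()
  if (set %in% c("basic", "freq_pro+basic", "freq_anti+basic", "all")) {
    b <- as.matrix(summaries[, saccade_parameter_names()])
    rownames(b) <- ids
    blocks$basic <- b
  }
  add_freq <- function(task) {
    sub <- features[features$task == task, ]
    cols <- expand.grid(eye = c("left", "right"),
                        f = spectrum_freqs(), stringsAsFactors = FALSE)
    m <- matrix(NA_real_, nrow = length(ids), ncol = nrow(cols),
                dimnames = list(ids, freq_col_name(task, cols$eye, cols$f)))
    key <- freq_col_name(task, sub$eye, sub$frequency_hz)
    for (i in seq_along(ids)) {
      s <- sub[sub$subject_id == ids[i], ]
      m[i, freq_col_name(task, s$eye, s$frequency_hz)] <- s$amplitude
    }
    m
  }
  if (set %in% c("freq_pro", "freq_pro+basic", "all"))
    blocks$freq_pro <- add_freq("pro_saccade")
  if (set %in% c("freq_anti", "freq_anti+basic", "all"))
    blocks$freq_anti <- add_freq("anti_saccade")
  x <- do.call(cbind, blocks)
  if (!nrow(x) || !ncol(x)) stop("empty feature matrix", call. = FALSE)
  structure(list(x = x, y = y, subject_id = ids, set = set),
            class = "feature_matrix")
}

#' Select significant feature columns
#'
#' Retains columns whose two-group comparison is significant. When no column
#' is significant, falls back to the `fallback_k` smallest p-values so the
#' classifier always has input.
#'
#' @param results Data.frame of comparison results with `feature_id`,
#'   `p_value`, `significant`, covering the matrix columns.
#' @param matrix A `feature_matrix`.
#' @param fallback_k Columns kept when nothing is significant. Default 5.
#' @return The reduced `feature_matrix` (with a `selected` attribute).
#' @export
select_features <- function(results, matrix, fallback_k = 5L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  cols <- colnames(matrix$x)
  if (!ncol(matrix$x)) stop("empty feature matrix", call. = FALSE)
  r <- results[match(cols, results$feature_id), ]
  if (anyNA(r$feature_id)) stop("results must cover all matrix columns",
                                call. = FALSE)
  keep <- cols[which(r$significant)]
  if (!length(keep))
    keep <- cols[order(r$p_value)][seq_len(min(fallback_k, length(cols)))]
  out <- matrix
  out$x <- matrix$x[, keep, drop = FALSE]
  attr(out, "selected") <- keep
  out
}

# Column p-values for a feature matrix (in-fold screening; fast path of
# compare_feature's gated test).
compare_matrix_columns <- function(x, y, alpha = 0.05) {
  pd <- y == "PD"
  p <- vapply(seq_len(ncol(x)), function(j) {
    a <- x[pd, j]; b <- x[!pd, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3L || length(b) < 3L) return(1)
    gated_pvalue(a, b, alpha)[1]
  }, numeric(1))
  data.frame(feature_id = colnames(x), p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

# Train-median imputation of NA cells.
impute_train_median <- function(train, test) {
  med <- apply(train, 2, function(v) {
    m <- median(v, na.rm = TRUE); if (is.na(m)) 0 else m })
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  list(train = fill(train), test = fill(test))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated random-forest evaluation
#'
#' Repeated stratified k-fold cross-validation. Within each training fold
#' (never on held-out data) features are selected by group-comparison
#' significance, missing cells are imputed with training-fold medians, and a
#' random forest is fit; accuracy, macro-averaged precision/recall and their
#' harmonic-mean F1 are computed over each repeat's pooled held-out
#' predictions and averaged across repeats.
#'
#' @param matrix A `feature_matrix`.
#' @param folds Number of CV folds. Default 5.
#' @param repeats CV repetitions. Default 10.
#' @param seed Integer seed (controls folds and forests).
#' @param ntree,mtry Forest hyperparameters (500 trees, sqrt-p default).
#' @param select Apply in-fold significance-based feature selection.
#'   Default TRUE.
#' @param alpha Selection significance level.
#' @return A `classifier_report`: list with `set`, `accuracy`, `precision`,
#'   `recall`, `f1`, `scheme`, `seed`, and `predictions` (per-fold held-out
#'   predictions for audit).
#' @export
evaluate <- function(matrix, folds = 5L, repeats = 10L, seed = 1L,
                     ntree = 500L, mtry = NULL, select = TRUE, alpha = 0.05) {
  stopifnot(inherits(matrix, "feature_matrix"))
  y <- matrix$y
  if (nlevels(droplevels(y)) < 2L) stop("single-class input", call. = FALSE)
  if (min(table(y)) < 2L) stop("need >= 2 subjects per class", call. = FALSE)
  folds <- as.integer(folds)
  old <- local_seed(as.integer(seed))
  on.exit(restore_seed(old))

  preds <- list()
  metrics <- base::matrix(NA_real_, nrow = repeats, ncol = 4,
                          dimnames = list(NULL, c("accuracy", "precision", "recall", "f1")))
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (k in seq_len(folds)) {
      te <- fold == k
      xtr <- matrix$x[!te, , drop = FALSE]; ytr <- y[!te]
      xte <- matrix$x[te, , drop = FALSE]
      if (select && ncol(xtr) > 1L) {
        res <- compare_matrix_columns(xtr, ytr, alpha)
        keep <- res$feature_id[res$significant]
        if (!length(keep))
          keep <- res$feature_id[order(res$p_value)][seq_len(min(5L, ncol(xtr)))]
        xtr <- xtr[, keep, drop = FALSE]
        xte <- xte[, keep, drop = FALSE]
      }
      im <- impute_train_median(xtr, xte)
      fseed <- sample.int(.Machine$integer.max - 1L, 1L)
      fit <- rf_fit(im$train, ytr, ntree = ntree, mtry = mtry, seed = fseed)
      pred[te] <- predict(fit, im$test)
    }
    metrics[r, ] <- unlist(classification_metrics(y, pred))
    preds[[r]] <- data.frame(repeat_ = r, subject_id = matrix$subject_id,
                             truth = y, predicted = pred,
                             stringsAsFactors = FALSE)
  }
  m <- colMeans(metrics)
  structure(list(set = matrix$set, accuracy = m[["accuracy"]],
                 precision = m[["precision"]], recall = m[["recall"]],
                 f1 = m[["f1"]],
                 scheme = sprintf("stratified %d-fold x %d repeats", folds, repeats),
                 seed = seed, per_repeat = as.data.frame(metrics),
                 predictions = do.call(rbind, preds)),
            class = "classifier_report")
}

#' Classification metrics from truth and prediction
#'
#' Accuracy; precision and recall macro-averaged over the two classes;
#' F1 as the harmonic mean of the reported precision and recall.
#'
#' @param truth,pred Factors on the same levels.
#' @return List with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  acc <- mean(pred == truth)
  per_class <- vapply(levels(truth), function(lv) {
    tp <- sum(pred == lv & truth == lv)
    prec <- if (sum(pred == lv) > 0) tp / sum(pred == lv) else 0
    rec <- if (sum(truth == lv) > 0) tp / sum(truth == lv) else 0
    c(prec, rec)
  }, numeric(2))
  precision <- mean(per_class[1, ]); recall <- mean(per_class[2, ])
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(accuracy = acc, precision = precision, recall = recall, f1 = f1)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: acc %.3f, prec %.3f, rec %.3f, F1 %.3f (%s)\n",
              x$set, x$accuracy, x$precision, x$recall, x$f1, x$scheme))
  invisible(x)
}

#' Evaluate all feature-set configurations
#'
#' @param summaries,features As for [build_feature_matrix()].
#' @param sets Feature-set tags to evaluate. Default all six.
#' @param ... Passed to [evaluate()].
#' @return List of `classifier_report`s plus a `table` data.frame analogue
#'   of the published model-performance table.
#' @export
evaluate_feature_sets <- function(summaries, features, sets = feature_sets(),
                                  ...) {
  reports <- lapply(sets, function(s)
    evaluate(build_feature_matrix(summaries, features, s), ...))
  names(reports) <- sets
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$set, accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  list(reports = reports, table = tab)
}
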