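# R interface to the compiled CART random forest (binary classification).

#' Fit a random forest classifier
#'
#' Bootstrap-aggregated CART trees with Gini splits and square-root feature
#' subsampling, grown to purity. Prediction is by majority vote over trees
#' (ties resolve to the negative class).
#'
#' @param x Numeric feature matrix (rows = subjects).
#' @param y Class labels; coerced to factor. The *second* level is treated
#'   as the positive class (with the default `c("control", "PD")` ordering,
#'   PD is positive).
#' @param ntree Number of trees. Default 500.
#' @param mtry Features tried per split. Default `floor(sqrt(ncol(x)))`.
#' @param min_node Minimum node size to attempt a split. Default 1.
#' @param seed Integer seed for the forest's internal RNG.
#' @return An `rf_model`.
#' @export
rf_fit <- function(x, y, ntree = 500L, mtry = NULL, min_node = 1L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) != 2L) stop("rf_fit is binary: y must have 2 levels", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- rf_fit_cpp(x, as.integer(y) - 1L, as.integer(ntree),
                      as.integer(mtry), as.integer(min_node), as.integer(seed))
  structure(list(trees = trees, levels = levels(y),
                 features = colnames(x), ntree = ntree, mtry = mtry,
                 seed = seed),
            class = "rf_model")
}

#' Predict with a random forest
#'
#' @param object An `rf_model`.
#' @param newdata Numeric matrix with the model's feature columns.
#' @param type `"class"` (majority vote) or `"prob"` (fraction of trees
#'   voting the positive class).
#' @param ... Unused.
#' @return Factor of predicted classes, or numeric vote fractions.
#' @export
predict.rf_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  storage.mode(newdata) <- "double"
  votes <- rf_predict_cpp(object$trees, newdata)
  if (type == "prob") return(votes)
  factor(ifelse(votes > 0.5, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry=%d, %d features, classes: %s\n",
              x$ntree, x$mtry, length(x$features),
              paste(x$levels, collapse = "/")))
  invisible(x)
}
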