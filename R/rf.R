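#' Random forest baseline configuration
#'
#' The baseline classifier is a random forest of 100 trees grown with the
#' Gini impurity criterion on the raw 9-feature measurement vectors.
#'
#' @param n_trees Number of trees.
#' @param seed Integer seed (forest growth is deterministic given it).
#' @return Object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100, seed = 1L) {
  if (n_trees < 1) stop_config("n_trees must be >= 1")
  structure(list(n_trees = n_trees, seed = as.integer(seed)),
            class = "rf_config")
}

#' Train the random forest baseline
#'
#' Thin wrapper around [randomForest::randomForest()] (CART trees, Gini
#' splits) conforming to the package's uniform classifier contract.
#'
#' @param train Per-sample view data.frame (columns `ch*`, `label`) or a
#'   list with elements `x` (matrix) and `y` (factor).
#' @param config An [rf_config()].
#' @return A `trained_classifier` of subclass `rf_classifier`.
#' @export
train_rf <- function(train, config = rf_config()) {
  xy <- as_xy(train)
  y <- droplevels(xy$y)
  if (nlevels(y) < 2)
    stop_config("training set contains a single class")
  fit <- with_seed(config$seed,
    randomForest::randomForest(x = xy$x, y = xy$y,
                               ntree = config$n_trees))
  structure(list(fit = fit, config = config, classes = levels(xy$y)),
            class = c("rf_classifier", "trained_classifier"))
}

# Uniform (x, y) extraction from a per-sample view or an x/y list.
as_xy <- function(obj) {
  if (is.data.frame(obj))
    list(x = psv_features(obj),
         y = factor(obj$label, levels = stiffness_classes()))
  else if (is.list(obj) && !is.null(obj$x))
    list(x = as.matrix(obj$x),
         y = factor(obj$y, levels = levels(obj$y) %||% stiffness_classes()))
  else stop_config("expected a per-sample view or list(x =, y =)")
}

#' Class-probability predictions
#'
#' Uniform probabilistic-prediction contract over the three classifiers.
#' Rows sum to 1; columns are named by class. For the CNN, see
#' [predict_proba.cnn_classifier()] (inputs are recordings, and samples
#' without 63 predecessors are not scored).
#'
#' @param model A `trained_classifier`.
#' @param newdata Classifier-specific input (feature matrix / per-sample
#'   view for RF and NN; recordings for the CNN).
#' @param ... Unused.
#' @return Numeric matrix of class probabilities.
#' @export
predict_proba <- function(model, newdata, ...) UseMethod("predict_proba")

#' @export
predict_proba.rf_classifier <- function(model, newdata, ...) {
  x <- if (is.data.frame(newdata)) psv_features(newdata) else
    as.matrix(newdata)
  p <- stats::predict(model$fit, x, type = "prob")
  p[, model$classes, drop = FALSE]
}
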