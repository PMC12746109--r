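# R interface to the gradient-boosted tree ensemble (src/boost_tree.cpp).

#' Gradient-boosting model configuration
#'
#' Defaults mirror the standard tree-booster configuration used for the
#' gene-phenotype models: maximum tree depth 6, learning rate 0.3, binary
#' logistic objective with log loss as the evaluation metric, up to 5000
#' boosting rounds with early stopping after 10 rounds without validation
#' improvement.
#'
#' @param max_depth Maximum tree depth (default 6).
#' @param eta Learning rate / shrinkage (default 0.3).
#' @param nrounds Maximum boosting rounds (default 5000).
#' @param early_stopping_rounds Patience on validation log loss (default 10).
#' @param lambda L2 regularisation on leaf weights (default 1).
#' @param min_child_weight Minimum hessian sum in a child (default 1).
#' @param seed Integer seed used for data splits.
#' @return A `model_config` list.
#' @export
model_config <- function(max_depth = 6L, eta = 0.3, nrounds = 5000L,
                         early_stopping_rounds = 10L, lambda = 1,
                         min_child_weight = 1, seed = 1L) {
  stopifnot(max_depth > 0, eta > 0, nrounds > 0, early_stopping_rounds > 0,
            lambda >= 0)
  structure(list(max_depth = as.integer(max_depth), eta = eta,
                 nrounds = as.integer(nrounds),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 lambda = lambda, min_child_weight = min_child_weight,
                 objective = "binary:logistic", eval_metric = "logloss",
                 booster = "gbtree", seed = as.integer(seed)),
            class = "model_config")
}

#' Fit a gradient-boosted tree classifier
#'
#' Binary logistic gradient boosting with exact greedy splits and
#' second-order (Newton) leaf weights. When a validation set is supplied,
#' training stops early once validation log loss fails to improve for
#' `config$early_stopping_rounds` consecutive rounds, and predictions use
#' the best iteration.
#'
#' @param X Numeric feature matrix (rows = samples), with column names.
#' @param y Binary 0/1 labels.
#' @param config A [model_config()].
#' @param X_val,y_val Optional validation set for early stopping.
#' @return A `gboost_model` with elements `trees`, `best_iteration`,
#'   `eval_log`, `importance` (per-feature `gain` total, `split_count` and
#'   average `gain_per_split`), `feature_names`.
#' @export
gboost <- function(X, y, config = model_config(), X_val = NULL,
                   y_val = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("single-class labels")
  if (is.null(X_val)) {
    X_val <- matrix(numeric(), 0L, ncol(X))
    y_val <- numeric()
  } else {
    X_val <- as.matrix(X_val)
    storage.mode(X_val) <- "double"
    stopifnot(nrow(X_val) == length(y_val))
  }
  fit <- .cpp_gboost_train(X, y, X_val, as.numeric(y_val),
                           config$max_depth, config$eta, config$nrounds,
                           config$early_stopping_rounds, config$lambda,
                           config$min_child_weight, 0.5)
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  imp <- data.frame(feature = fn, gain = fit$gain_sum,
                    split_count = fit$split_count,
                    gain_per_split = ifelse(fit$split_count > 0,
                                            fit$gain_sum / fit$split_count,
                                            0))
  imp <- imp[order(-imp$gain, imp$feature), , drop = FALSE]
  structure(list(trees = fit$trees, best_iteration = fit$best_iteration,
                 best_loss = fit$best_loss, eval_log = fit$eval_log,
                 base_margin = fit$base_margin, eta = fit$eta,
                 importance = imp, feature_names = fn,
                 config = config),
            class = "gboost_model")
}

#' @export
print.gboost_model <- function(x, ...) {
  cat(sprintf("<gboost_model> %d trees (best iteration %d)\n",
              length(x$trees), x$best_iteration))
  invisible(x)
}

#' Predict class probabilities from a gradient-boosted model
#'
#' @param object A `gboost_model`.
#' @param newdata Numeric feature matrix with the training columns.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.gboost_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  .cpp_gboost_predict(object$trees, newdata, object$base_margin,
                      object$eta, object$best_iteration)
}
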