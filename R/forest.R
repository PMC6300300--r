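#' Random forest classifier (internal learner)
#'
#' A compact CART-based classification forest backing the ranking models:
#' bootstrap resampling, per-node feature subsampling (`mtry`), Gini-style
#' split criterion on quantile-binned features (at most 255 cut points per
#' feature), and per-sample weights for class balancing. Fitting draws from
#' R's RNG, so wrap calls in `set.seed()` for reproducibility.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param y 0/1 integer labels.
#' @param weights optional per-sample weights; default balances classes to
#'   equal total weight.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per node; default `floor(sqrt(ncol(x)))`.
#' @param max_depth maximum tree depth (default 14).
#' @param min_node minimum examples per child node (default 10).
#' @param sample_frac bootstrap sample fraction (default 1, with
#'   replacement).
#' @return Object of class `rf_model`.
#' @export
random_forest <- function(x, y, weights = NULL, n_trees = 500, mtry = NULL,
                          max_depth = 14, min_node = 10, sample_frac = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("need both classes to fit a forest")
  if (is.null(weights)) {
    n1 <- sum(y == 1L)
    weights <- ifelse(y == 1L, (length(y) - n1) / n1, 1)
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  trees <- rf_fit_cpp(x, y, as.numeric(weights), as.integer(n_trees),
                      as.integer(mtry), as.integer(max_depth),
                      as.integer(min_node), sample_frac)
  structure(list(trees = trees, features = colnames(x),
                 n_trees = n_trees, mtry = mtry),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features)) {
    if (!all(object$features %in% colnames(newdata)))
      stop("prediction data lacks features: ",
           paste(setdiff(object$features, colnames(newdata)), collapse = ", "))
    newdata <- newdata[, object$features, drop = FALSE]
  }
  storage.mode(newdata) <- "double"
  rf_predict_cpp(object$trees, newdata)
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry %d, %d features\n",
              x$n_trees, x$mtry, length(x$features)))
  invisible(x)
}
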