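#' Fit a random forest regressor
#'
#' CART regression trees with bootstrap aggregation and per-node feature
#' subsampling (compiled implementation; deterministic given `seed`).
#'
#' @param x numeric feature matrix.
#' @param y numeric target.
#' @param ntree number of trees (500 by default).
#' @param mtry features tried per split; defaults to `max(1, p/3)`, the
#'   regression convention.
#' @param min_node minimal node size to attempt a split.
#' @param max_depth maximal depth (0 = unlimited).
#' @param seed integer seed for bootstrap and feature sampling.
#' @return object of class `aq_rf`.
#' @export
rf_fit <- function(x, y, ntree = 500L, mtry = NULL, min_node = 5L,
                   max_depth = 0L, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 1L)
  mtry <- as.integer(mtry %||% max(1L, floor(ncol(x) / 3)))
  trees <- cpp_forest_fit(x, as.numeric(y), as.integer(ntree), mtry,
                          as.integer(min_node), as.integer(max_depth),
                          as.numeric(seed), TRUE)
  structure(list(trees = trees, p = ncol(x)), class = "aq_rf")
}

#' @export
predict.aq_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("feature dimension mismatch")
  cpp_forest_predict(object$trees, newdata)
}

#' Fit a gradient-boosted tree regressor
#'
#' Squared-error boosting with shallow CART trees.
#'
#' @inheritParams rf_fit
#' @param nrounds boosting rounds.
#' @param depth tree depth.
#' @param rate learning rate.
#' @return object of class `aq_gbt`.
#' @export
gbt_fit <- function(x, y, nrounds = 500L, depth = 3L, rate = 0.05,
                    min_node = 5L, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 1L)
  model <- cpp_gbt_fit(x, as.numeric(y), as.integer(nrounds),
                       as.integer(depth), rate, as.integer(min_node),
                       as.numeric(seed))
  structure(list(model = model, p = ncol(x)), class = "aq_gbt")
}

#' @export
predict.aq_gbt <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("feature dimension mismatch")
  cpp_gbt_predict(object$model, newdata)
}
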