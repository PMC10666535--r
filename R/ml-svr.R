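#' Least-squares support vector regression (RBF kernel)
#'
#' Kernel regressor used as a base learner in the stacked ensemble.  The
#' least-squares formulation replaces the epsilon-insensitive hinge with a
#' squared loss, turning training into one linear solve of the classic
#' LS-SVM system
#' \deqn{\begin{pmatrix}0 & 1^T\\ 1 & K + I/C\end{pmatrix}
#'       \begin{pmatrix}b\\ \alpha\end{pmatrix} =
#'       \begin{pmatrix}0\\ y\end{pmatrix}}
#' Features are standardized internally; `gamma` defaults to `1/p` on the
#' standardized scale.  Training cost is cubic in n, so this learner is
#' meant for the moderate table sizes of the stacking ensemble.
#'
#' @param x feature matrix.
#' @param y numeric target.
#' @param cost regularization constant C (> 0).
#' @param gamma RBF kernel width; `NULL` for `1/ncol(x)`.
#' @return object of class `aq_svr`.
#' @export
svr_fit <- function(x, y, cost = 1, gamma = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), cost > 0)
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  gamma <- gamma %||% (1 / ncol(x))
  K <- .rbf_kernel(xs, xs, gamma)
  n <- nrow(xs)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / cost, n)))
  sol <- solve(A, c(0, y))
  structure(list(xs = xs, alpha = sol[-1], b = sol[1], gamma = gamma,
                 center = center, scale = scale), class = "aq_svr")
}

.rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' @export
predict.aq_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  drop(.rbf_kernel(xs, object$xs, object$gamma) %*% object$alpha) +
    object$b
}
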