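# Small fully-connected network with rectified hidden layers, trained by
# Adam on (optionally masked) squared error.  Pure matrix code: fast enough
# for the table sizes of this package and keeps the parameter vector fully
# inspectable, which the MAML and fine-tuning learners rely on.

#' Create an untrained multilayer perceptron
#'
#' @param n_in,n_out input/output widths.
#' @param hidden integer vector of hidden-layer widths.
#' @param seed seed for the He-scaled Gaussian initialization.
#' @return object of class `aq_nn`: lists `W`, `b` per layer.
#' @export
nn_new <- function(n_in, n_out, hidden = c(256L, 256L), seed = 1L) {
  sizes <- c(n_in, hidden, n_out)
  L <- length(sizes) - 1L
  withr::with_seed(as.integer(seed), {
    W <- lapply(seq_len(L), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1L], 0, sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1L]))
  })
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
  structure(list(W = W, b = b, sizes = sizes), class = "aq_nn")
}

.nn_forward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(H[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    H[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  H
}

#' Network predictions (raw output matrix)
#' @param net an `aq_nn`.
#' @param X input matrix.
#' @return n x n_out matrix.
#' @export
nn_predict_raw <- function(net, X) {
  H <- .nn_forward(net, as.matrix(X))
  H[[length(H)]]
}

# masked mean squared error and its gradient.  Y and mask are n x k;
# mask NULL means fully observed.
.nn_loss_grad <- function(net, X, Y, mask = NULL) {
  L <- length(net$W)
  H <- .nn_forward(net, X)
  pred <- H[[L + 1L]]
  resid <- pred - Y
  if (is.null(mask)) {
    n_obs <- length(resid)
  } else {
    resid[!mask] <- 0
    n_obs <- max(sum(mask), 1L)
  }
  loss <- sum(resid^2) / n_obs
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- 2 * resid / n_obs
  for (l in L:1) {
    dW[[l]] <- crossprod(H[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(net$W[[l]])) * (H[[l]] > 0)
  }
  list(loss = loss, dW = dW, db = db)
}

#' Train a network with Adam
#'
#' @param net an [nn_new()] network (updated functionally; the trained
#'   copy is returned).
#' @param X,Y input matrix and target matrix (one column per output).
#' @param mask optional logical matrix marking observed (row, output)
#'   pairs; unobserved entries contribute no loss.
#' @param epochs,batch,lr training schedule (`epochs = 0` is a no-op and
#'   returns the initialization).
#' @param val_idx optional row indices used as an early-stopping
#'   validation split (never trained on); `patience` epochs without
#'   improvement restore the best parameters.
#' @param train_layers indices of layers whose parameters may move
#'   (default all); used by head-only fine-tuning.
#' @param seed seed for batch shuffling.
#' @return the trained `aq_nn`.
#' @export
nn_train <- function(net, X, Y, mask = NULL, epochs = 200L, batch = 128L,
                     lr = 1e-3, val_idx = NULL, patience = 10L,
                     train_layers = NULL, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (epochs <= 0L) return(net)
  L <- length(net$W)
  train_layers <- train_layers %||% seq_len(L)
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L
  best <- list(net = net, loss = Inf, stale = 0L)
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1L, length(ord), by = batch)) {
        rows <- ord[start:min(start + batch - 1L, length(ord))]
        g <- .nn_loss_grad(net, X[rows, , drop = FALSE],
                           Y[rows, , drop = FALSE],
                           if (!is.null(mask)) mask[rows, , drop = FALSE])
        if (!is.finite(g$loss)) stop("nn training diverged (non-finite loss)")
        t <- t + 1L
        corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
        for (l in train_layers) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$dW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$dW[[l]]^2
          net$W[[l]] <- net$W[[l]] -
            lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$db[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$db[[l]]^2
          net$b[[l]] <- net$b[[l]] -
            lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      if (length(val_idx)) {
        vl <- .nn_loss_grad(net, X[val_idx, , drop = FALSE],
                            Y[val_idx, , drop = FALSE],
                            if (!is.null(mask))
                              mask[val_idx, , drop = FALSE])$loss
        if (vl < best$loss - 1e-9) {
          best <- list(net = net, loss = vl, stale = 0L)
        } else {
          best$stale <- best$stale + 1L
          if (best$stale >= patience) break
        }
      }
    }
  })
  if (length(val_idx) && is.finite(best$loss)) best$net else net
}

# ---- parameter-vector view (used by MAML) --------------------------------

#' Flatten network parameters to one numeric vector
#' @param net an `aq_nn`.
#' @return numeric vector.
#' @export
nn_flatten <- function(net) {
  unlist(c(lapply(net$W, as.numeric), net$b), use.names = FALSE)
}

#' Rebuild a network from a flat parameter vector
#' @param net template network (for shapes).
#' @param theta flat parameter vector from [nn_flatten()].
#' @return `aq_nn` with the given parameters.
#' @export
nn_unflatten <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    k <- length(net$W[[l]])
    net$W[[l]][] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  for (l in seq_along(net$b)) {
    k <- length(net$b[[l]])
    net$b[[l]][] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  net
}

# loss and flat gradient of mean squared error at theta on (X, y)
.nn_loss_grad_vec <- function(template, theta, X, y) {
  net <- nn_unflatten(template, theta)
  g <- .nn_loss_grad(net, X, matrix(y, ncol = 1L))
  list(loss = g$loss,
       grad = unlist(c(lapply(g$dW, as.numeric), g$db), use.names = FALSE))
}
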