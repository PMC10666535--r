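#' Model-agnostic meta-learning (first-order)
#'
#' Learns an initialization parameter vector theta from which each task's
#' optimum is reachable in few gradient steps.  The implementation is
#' genuinely model-agnostic: it only needs a gradient function
#' `grad_fn(theta, task)` returning `list(loss, grad)` for any task object,
#' so the same core serves both the neural-network learner and analytic
#' toy losses used to verify it.
#'
#' Each outer iteration samples a batch of tasks, adapts theta on each task
#' with `inner_steps` plain gradient steps of size `inner_lr`, and moves
#' theta against the mean post-adaptation gradient with step `outer_lr`
#' (the first-order approximation: second-derivative terms are dropped,
#' which is the standard stability/cost trade-off).  Divergence
#' (non-finite loss) aborts with a diagnostic rather than returning
#' garbage.
#'
#' @param tasks list of task objects (opaque to the optimizer).
#' @param init numeric initialization vector.
#' @param grad_fn function(theta, task) -> list(loss = number,
#'   grad = numeric vector).
#' @param inner_lr,outer_lr positive learning rates.
#' @param inner_steps number of adaptation steps (>= 0).
#' @param n_iter outer iterations.
#' @param task_batch tasks sampled per outer iteration.
#' @param seed seed controlling task sampling.
#' @return object of class `maml_state`: `theta` plus the configuration.
#' @export
maml_fit <- function(tasks, init, grad_fn, inner_lr = 1e-2,
                     outer_lr = 1e-2, inner_steps = 1L, n_iter = 100L,
                     task_batch = 8L, seed = 1L) {
  stopifnot(length(tasks) >= 2L, inner_lr > 0, outer_lr > 0,
            inner_steps >= 0L)
  theta <- as.numeric(init)
  withr::with_seed(as.integer(seed), {
    for (it in seq_len(n_iter)) {
      batch <- sample(seq_along(tasks),
                      min(task_batch, length(tasks)))
      outer_grad <- numeric(length(theta))
      for (ti in batch) {
        ad <- .maml_inner(theta, tasks[[ti]], grad_fn, inner_lr,
                          inner_steps)
        g <- grad_fn(ad, tasks[[ti]])
        if (!is.finite(g$loss) || any(!is.finite(g$grad)))
          stop(sprintf(
            "MAML diverged at outer iteration %d (non-finite loss)", it))
        outer_grad <- outer_grad + g$grad / length(batch)
      }
      theta <- theta - outer_lr * outer_grad
      if (any(!is.finite(theta)))
        stop(sprintf("MAML diverged at outer iteration %d", it))
    }
  })
  structure(list(theta = theta, inner_lr = inner_lr,
                 inner_steps = inner_steps, grad_fn = grad_fn),
            class = "maml_state")
}

.maml_inner <- function(theta, task, grad_fn, inner_lr, inner_steps) {
  for (s in seq_len(inner_steps)) {
    g <- grad_fn(theta, task)
    if (!is.finite(g$loss) || any(!is.finite(g$grad)))
      stop("MAML inner loop diverged (non-finite loss)")
    theta <- theta - inner_lr * g$grad
  }
  theta
}

#' Adapt a MAML initialization to one task
#'
#' Runs the configured number of inner gradient steps from the
#' meta-learned initialization on the given task only.  With
#' `inner_steps = 0` the returned parameters equal the shared
#' initialization exactly.
#'
#' @param state a [maml_fit()] result.
#' @param task one task object (same shape the gradient function expects).
#' @param inner_steps optional override of the stored step count.
#' @return adapted parameter vector.
#' @export
maml_adapt <- function(state, task, inner_steps = NULL) {
  stopifnot(inherits(state, "maml_state"))
  .maml_inner(state$theta, task, state$grad_fn, state$inner_lr,
              inner_steps %||% state$inner_steps)
}
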