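#' Learner specification
#'
#' The eleven learner families (ten algorithms; transformational machine
#' learning contributes two variants) behind the package's uniform
#' fit/predict contract:
#'
#' * `st_mean`, `st_rf` — single-task baselines (per-species mean /
#'   per-species random forest); no knowledge of other species.
#' * `mt_mean`, `mt_rf` — pooled mean / one random forest over all species
#'   with taxonomy features.
#' * `mt_stack` — stacked ensemble: support-vector, gradient-boosted-tree
#'   and random-forest bases combined by a linear meta-learner trained on
#'   out-of-fold base predictions.
#' * `nn_one_output` — one network over all tasks, one output node,
#'   taxonomy features as inputs.
#' * `multitarget_nn` — shared trunk, one output node per training
#'   species; no taxonomy inputs.
#' * `finetune_top` — the one-output network with all layers except the
#'   head frozen and per-species head retraining.
#' * `maml` — first-order model-agnostic meta-learning of a network
#'   initialization, adapted per species.
#' * `tml`, `tml_stacked` — transformational machine learning: compounds
#'   represented by the vector of per-species first-stage forest
#'   predictions, with per-species second-stage forests (optionally
#'   averaged with the first-stage single-task forest).
#'
#' @param family one of [learner_families()].
#' @param seed integer seed fixed before any stochastic fit.
#' @param ... family-specific hyperparameters overriding the defaults
#'   (e.g. `ntree`, `hidden`, `epochs`, `inner_lr`).
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(family, seed = 1L, ...) {
  family <- match.arg(family, learner_families())
  hyper <- utils::modifyList(.default_hyper(family), list(...))
  structure(list(family = family, seed = as.integer(seed), hyper = hyper),
            class = "learner_spec")
}

#' Declared learner families
#' @return character vector of family names.
#' @export
learner_families <- function() {
  c("st_mean", "st_rf", "mt_mean", "mt_rf", "mt_stack", "nn_one_output",
    "multitarget_nn", "finetune_top", "maml", "tml", "tml_stacked")
}

#' Table mode a family consumes
#'
#' Families using taxonomy encodings need `multi_task` tables; families
#' operating on chemical + duration features alone (including the
#' per-species meta-learners) consume `single_task` tables.
#'
#' @param family a family name.
#' @return `"single_task"` or `"multi_task"`.
#' @export
learner_mode <- function(family) {
  multi <- c("mt_mean", "mt_rf", "mt_stack", "nn_one_output",
             "finetune_top")
  if (family %in% multi) "multi_task" else "single_task"
}

.default_hyper <- function(family) {
  nn <- list(hidden = c(256L, 256L), epochs = 200L, batch = 128L,
             lr = 1e-3, patience = 10L, val_frac = 0.1)
  switch(family,
    st_mean = , mt_mean = list(),
    st_rf = , mt_rf = list(ntree = 500L, mtry = NULL, min_node = 5L),
    mt_stack = list(k_folds = 5L, ntree = 500L, nrounds = 500L,
                    depth = 3L, rate = 0.05, cost = 1,
                    ridge_lambda = 1e-3),
    nn_one_output = nn,
    multitarget_nn = nn,
    finetune_top = c(nn, list(ft_epochs = 50L)),
    maml = list(hidden = c(32L, 32L), inner_lr = 1e-2, outer_lr = 1e-3,
                inner_steps = 3L, n_iter = 200L, task_batch = 8L),
    tml = , tml_stacked = list(ntree = 500L, mtry = NULL, min_node = 5L,
                               include_self = TRUE))
}

#' Fit a learner on a model table
#'
#' Uniform entry point for all families.  The fitted object records the
#' training feature schema and species registry; [predict.aquamtl_fit()]
#' refuses tables whose schema does not match, and single-task families
#' refuse species absent from the registry (use [can_predict()] to filter
#' beforehand).
#'
#' @param spec a [learner_spec()].
#' @param table a [build_model_table()] result in the mode
#'   [learner_mode()] requires for the family.
#' @return object of class `aquamtl_fit`.
#' @export
fit_learner <- function(spec, table) {
  stopifnot(inherits(spec, "learner_spec"), inherits(table, "model_table"))
  need <- learner_mode(spec$family)
  if (!identical(table$mode, need))
    stop(sprintf("family '%s' requires a %s table (got %s)",
                 spec$family, need, table$mode))
  if (nrow(table$x) < 1L) stop("empty training table")
  model <- switch(spec$family,
    st_mean = .fit_st_mean(table),
    mt_mean = .fit_mt_mean(table),
    st_rf = .fit_st_rf(table, spec),
    mt_rf = .fit_mt_rf(table, spec),
    mt_stack = .fit_mt_stack(table, spec),
    nn_one_output = .fit_nn_shared(table, spec),
    multitarget_nn = .fit_multitarget_nn(table, spec),
    finetune_top = .fit_finetune_top(table, spec),
    maml = .fit_maml(table, spec),
    tml = .fit_tml(table, spec, stacked = FALSE),
    tml_stacked = .fit_tml(table, spec, stacked = TRUE))
  structure(list(family = spec$family, spec = spec, model = model,
                 feature_names = colnames(table$x), mode = table$mode,
                 species_registry = sort(unique(table$species)),
                 train_chemicals = sort(unique(table$chemical))),
            class = "aquamtl_fit")
}

#' Which rows can a fitted learner score?
#'
#' Multi-task families predict any species (falling back to class/phylum
#' information for species unseen in training); families with per-species
#' submodels or heads can only score species present in the training
#' registry.
#'
#' @param object an `aquamtl_fit`.
#' @param species character vector of species ids.
#' @return logical vector.
#' @export
can_predict <- function(object, species) {
  stopifnot(inherits(object, "aquamtl_fit"))
  per_species <- c("st_mean", "st_rf", "multitarget_nn", "maml", "tml",
                   "tml_stacked")
  if (object$family %in% per_species)
    species %in% object$species_registry
  else rep(TRUE, length(species))
}

#' Predict from a fitted learner
#'
#' @param object an `aquamtl_fit`.
#' @param newdata a `model_table` built with the *training schema* (same
#'   mode, same feature columns); anything else is refused.
#' @param ... unused.
#' @return numeric vector, one prediction (log10 LC50) per row.
#' @export
predict.aquamtl_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "model_table"))
  if (!identical(colnames(newdata$x), object$feature_names))
    stop("feature schema mismatch between fit and prediction table")
  ok <- can_predict(object, newdata$species)
  if (!all(ok))
    stop(sprintf("family '%s' cannot predict %d row(s) of unseen species",
                 object$family, sum(!ok)))
  m <- object$model
  switch(object$family,
    st_mean = unname(m$means[newdata$species]),
    mt_mean = rep(m$mean, nrow(newdata$x)),
    st_rf = .predict_per_species(m$models, newdata),
    mt_rf = predict(m$forest, newdata$x),
    mt_stack = .predict_stack(m, newdata),
    nn_one_output = .predict_nn_shared(m, newdata),
    multitarget_nn = .predict_multitarget_nn(m, newdata),
    finetune_top = .predict_finetune(m, newdata),
    maml = .predict_maml(m, newdata),
    tml = .predict_tml(m, newdata, stacked = FALSE),
    tml_stacked = .predict_tml(m, newdata, stacked = TRUE))
}

#' @export
print.aquamtl_fit <- function(x, ...) {
  cat(sprintf("<aquamtl_fit> family=%s, %d features, %d species\n",
              x$family, length(x$feature_names),
              length(x$species_registry)))
  invisible(x)
}

# ---- mean baselines ------------------------------------------------------

.fit_st_mean <- function(table) {
  list(means = vapply(split(table$y, table$species), mean, numeric(1)))
}

.fit_mt_mean <- function(table) list(mean = mean(table$y))

# ---- random forests ------------------------------------------------------

.fit_st_rf <- function(table, spec) {
  species <- sort(unique(table$species))
  models <- vector("list", length(species))
  names(models) <- species
  for (i in seq_along(species)) {
    idx <- which(table$species == species[i])
    if (length(idx) < 2L) {
      # too few rows for a forest: documented fallback to the species mean
      message("st_rf: species ", species[i],
              " has < 2 rows; falling back to st_mean")
      models[[i]] <- list(mean = mean(table$y[idx]))
    } else {
      models[[i]] <- rf_fit(table$x[idx, , drop = FALSE], table$y[idx],
                            ntree = spec$hyper$ntree,
                            mtry = spec$hyper$mtry,
                            min_node = spec$hyper$min_node,
                            seed = .subseed(spec$seed, i))
    }
  }
  list(models = models)
}

.predict_per_species <- function(models, newdata) {
  out <- numeric(nrow(newdata$x))
  for (sp in unique(newdata$species)) {
    idx <- which(newdata$species == sp)
    m <- models[[sp]]
    out[idx] <- if (inherits(m, "aq_rf"))
      predict(m, newdata$x[idx, , drop = FALSE]) else m$mean
  }
  out
}

.fit_mt_rf <- function(table, spec) {
  list(forest = rf_fit(table$x, table$y, ntree = spec$hyper$ntree,
                       mtry = spec$hyper$mtry,
                       min_node = spec$hyper$min_node,
                       seed = spec$seed))
}

# ---- stacked ensemble ----------------------------------------------------

.fit_base <- function(which, x, y, spec) {
  switch(which,
    rf = rf_fit(x, y, ntree = spec$hyper$ntree, min_node = 5L,
                seed = .subseed(spec$seed, 11L)),
    gbt = gbt_fit(x, y, nrounds = spec$hyper$nrounds,
                  depth = spec$hyper$depth, rate = spec$hyper$rate,
                  seed = .subseed(spec$seed, 12L)),
    svr = svr_fit(x, y, cost = spec$hyper$cost))
}

.fit_mt_stack <- function(table, spec) {
  k <- spec$hyper$k_folds
  if (nrow(table$x) < 2L * k)
    stop("mt_stack needs at least 2 * k_folds training rows")
  chems <- sort(unique(table$chemical))
  k <- min(k, length(chems))
  withr::with_seed(.subseed(spec$seed, 10L), {
    fold_of <- setNames(sample(rep_len(seq_len(k), length(chems))), chems)
  })
  bases <- c("rf", "gbt", "svr")
  oof <- matrix(NA_real_, nrow(table$x), length(bases),
                dimnames = list(NULL, bases))
  for (f in seq_len(k)) {
    test_rows <- which(fold_of[table$chemical] == f)
    train_rows <- setdiff(seq_len(nrow(table$x)), test_rows)
    for (b in bases) {
      m <- .fit_base(b, table$x[train_rows, , drop = FALSE],
                     table$y[train_rows], spec)
      oof[test_rows, b] <- predict(m, table$x[test_rows, , drop = FALSE])
    }
  }
  meta <- tryCatch({
    fit <- lm(table$y ~ oof)
    cf <- coef(fit)
    if (anyNA(cf)) stop("collinear base predictions")
    c(cf[1], cf[-1])
  }, error = function(e) {
    message("mt_stack: meta regression degenerate, using ridge fallback")
    X <- cbind(1, oof)
    lam <- spec$hyper$ridge_lambda
    drop(solve(crossprod(X) + diag(lam, ncol(X)), crossprod(X, table$y)))
  })
  full <- lapply(setNames(bases, bases), function(b)
    .fit_base(b, table$x, table$y, spec))
  list(bases = full, meta = unname(meta))
}

.predict_stack <- function(m, newdata) {
  P <- vapply(m$bases, function(b) predict(b, newdata$x),
              numeric(nrow(newdata$x)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  drop(m$meta[1] + P %*% m$meta[-1])
}

# ---- neural networks -----------------------------------------------------

.nn_standardize <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale < 1e-12] <- 1
  list(center = center, scale = scale,
       xs = sweep(sweep(x, 2, center), 2, scale, "/"))
}

.nn_val_rows <- function(table, frac, seed) {
  chems <- sort(unique(table$chemical))
  if (length(chems) < 10L || frac <= 0) return(integer(0))
  withr::with_seed(seed, {
    val_chems <- sample(chems, max(1L, round(frac * length(chems))))
  })
  which(table$chemical %in% val_chems)
}

.fit_nn_shared <- function(table, spec) {
  h <- spec$hyper
  std <- .nn_standardize(table$x)
  y_mean <- mean(table$y); y_sd <- max(sd(table$y), 1e-8)
  net <- nn_new(ncol(std$xs), 1L, hidden = h$hidden, seed = spec$seed)
  val <- .nn_val_rows(table, h$val_frac, .subseed(spec$seed, 21L))
  net <- nn_train(net, std$xs, (table$y - y_mean) / y_sd,
                  epochs = h$epochs, batch = h$batch, lr = h$lr,
                  val_idx = val, patience = h$patience,
                  seed = .subseed(spec$seed, 22L))
  list(net = net, center = std$center, scale = std$scale,
       y_mean = y_mean, y_sd = y_sd)
}

.nn_scale_input <- function(m, x) {
  sweep(sweep(x, 2, m$center), 2, m$scale, "/")
}

.predict_nn_shared <- function(m, newdata) {
  drop(nn_predict_raw(m$net, .nn_scale_input(m, newdata$x))) * m$y_sd +
    m$y_mean
}

.fit_multitarget_nn <- function(table, spec) {
  h <- spec$hyper
  species <- sort(unique(table$species))
  std <- .nn_standardize(table$x)
  y_mean <- mean(table$y); y_sd <- max(sd(table$y), 1e-8)
  Y <- matrix(0, nrow(std$xs), length(species),
              dimnames = list(NULL, species))
  mask <- matrix(FALSE, nrow(std$xs), length(species))
  col <- match(table$species, species)
  Y[cbind(seq_along(col), col)] <- (table$y - y_mean) / y_sd
  mask[cbind(seq_along(col), col)] <- TRUE
  net <- nn_new(ncol(std$xs), length(species), hidden = h$hidden,
                seed = spec$seed)
  val <- .nn_val_rows(table, h$val_frac, .subseed(spec$seed, 21L))
  net <- nn_train(net, std$xs, Y, mask = mask, epochs = h$epochs,
                  batch = h$batch, lr = h$lr, val_idx = val,
                  patience = h$patience, seed = .subseed(spec$seed, 22L))
  list(net = net, center = std$center, scale = std$scale,
       y_mean = y_mean, y_sd = y_sd, species = species)
}

.predict_multitarget_nn <- function(m, newdata) {
  P <- nn_predict_raw(m$net, .nn_scale_input(m, newdata$x))
  col <- match(newdata$species, m$species)
  P[cbind(seq_along(col), col)] * m$y_sd + m$y_mean
}

.fit_finetune_top <- function(table, spec) {
  h <- spec$hyper
  base <- .fit_nn_shared(table, spec)
  L <- length(base$net$W)
  heads <- list()
  ys <- (table$y - base$y_mean) / base$y_sd
  xs <- .nn_scale_input(base, table$x)
  for (sp in sort(unique(table$species))) {
    idx <- which(table$species == sp)
    tuned <- nn_train(base$net, xs[idx, , drop = FALSE],
                      ys[idx], epochs = h$ft_epochs,
                      batch = min(h$batch, length(idx)), lr = h$lr,
                      train_layers = L,
                      seed = .subseed(spec$seed, 30L))
    heads[[sp]] <- list(W = tuned$W[[L]], b = tuned$b[[L]])
  }
  c(base, list(heads = heads))
}

.predict_finetune <- function(m, newdata) {
  xs <- .nn_scale_input(m, newdata$x)
  out <- numeric(nrow(xs))
  L <- length(m$net$W)
  for (sp in unique(newdata$species)) {
    idx <- which(newdata$species == sp)
    net <- m$net
    if (!is.null(m$heads[[sp]])) {  # unseen species: pretrained head
      net$W[[L]] <- m$heads[[sp]]$W
      net$b[[L]] <- m$heads[[sp]]$b
    }
    out[idx] <- drop(nn_predict_raw(net, xs[idx, , drop = FALSE]))
  }
  out * m$y_sd + m$y_mean
}

# ---- MAML ----------------------------------------------------------------

.fit_maml <- function(table, spec) {
  h <- spec$hyper
  species <- sort(unique(table$species))
  if (length(species) < 2L) stop("maml needs >= 2 tasks (species)")
  std <- .nn_standardize(table$x)
  y_mean <- mean(table$y); y_sd <- max(sd(table$y), 1e-8)
  tasks <- lapply(setNames(species, species), function(sp) {
    idx <- which(table$species == sp)
    list(X = std$xs[idx, , drop = FALSE],
         y = (table$y[idx] - y_mean) / y_sd)
  })
  template <- nn_new(ncol(std$xs), 1L, hidden = h$hidden,
                     seed = spec$seed)
  grad_fn <- function(theta, task)
    .nn_loss_grad_vec(template, theta, task$X, task$y)
  state <- maml_fit(tasks, nn_flatten(template), grad_fn,
                    inner_lr = h$inner_lr, outer_lr = h$outer_lr,
                    inner_steps = h$inner_steps, n_iter = h$n_iter,
                    task_batch = h$task_batch,
                    seed = .subseed(spec$seed, 40L))
  adapted <- lapply(tasks, function(task) maml_adapt(state, task))
  list(state = state, template = template, adapted = adapted,
       center = std$center, scale = std$scale,
       y_mean = y_mean, y_sd = y_sd)
}

.predict_maml <- function(m, newdata) {
  xs <- .nn_scale_input(m, newdata$x)
  out <- numeric(nrow(xs))
  for (sp in unique(newdata$species)) {
    idx <- which(newdata$species == sp)
    net <- nn_unflatten(m$template, m$adapted[[sp]])
    out[idx] <- drop(nn_predict_raw(net, xs[idx, , drop = FALSE]))
  }
  out * m$y_sd + m$y_mean
}
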