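small_tables <- function(world = linear_world(), mode = "single_task") {
  build_model_table(world$records, world$chemicals, world$taxonomy, mode)
}

test_that("mean baselines behave as documented", {
  rec <- make_records(c("s1", "s1", "s2"), c("a", "b", "a"), 2,
                      c(10, 1000, 100))
  chems <- make_chemicals(5)
  chems$chemical_id <- c("a", "b", "c", "d", "e")
  tax <- make_taxonomy(c("s1", "s2"))
  tab <- build_model_table(rec, chems, tax, "single_task")
  st <- fit_learner(learner_spec("st_mean"), tab)
  p <- predict(st, tab)
  expect_equal(p[tab$species == "s1"], rep(2, 2))   # mean of {1, 3}
  expect_equal(p[tab$species == "s2"], 2)           # single row: identity
  # training RMSE of st_mean = population sd of targets per species
  expect_equal(rmse(tab$y[tab$species == "s1"], p[tab$species == "s1"]),
               sqrt(mean((c(1, 3) - 2)^2)))

  mt_tab <- build_model_table(rec, chems, tax, "multi_task")
  mt <- fit_learner(learner_spec("mt_mean"), mt_tab)
  expect_equal(predict(mt, mt_tab), rep(2, 3))
  # unseen species still gets the pooled mean
  rec_new <- make_records("s3", "c", 2, 1)
  tax2 <- make_taxonomy(c("s1", "s2", "s3"))
  new_tab <- build_model_table(rec_new, chems, tax2, "multi_task",
                               schema = mt_tab$schema)
  expect_true(can_predict(mt, "s3"))
  expect_equal(predict(mt, new_tab), 2)
  # single-task family refuses the unseen species
  expect_false(can_predict(st, "s3"))
})

test_that("random forest fits a noiseless step function almost exactly", {
  x <- matrix(rep(c(0, 1), each = 50), ncol = 1)
  y <- ifelse(x[, 1] > 0.5, 3, -1)
  rf <- rf_fit(x, y, ntree = 200, min_node = 2, seed = 1)
  expect_lt(rmse(y, predict(rf, x)), 0.05)
})

test_that("fits are invariant to training row order and seeded", {
  w <- linear_world(n_species = 3L, n_chem = 30L, noise = 0.2)
  tab1 <- small_tables(w)
  shuffled <- w$records[sample(nrow(w$records)), ]
  tab2 <- build_model_table(shuffled, w$chemicals, w$taxonomy,
                            "single_task")
  spec <- learner_spec("st_rf", ntree = 30)
  f1 <- fit_learner(spec, tab1)
  f2 <- fit_learner(spec, tab2)
  expect_equal(predict(f1, tab1), predict(f2, tab1), tolerance = 1e-12)
  # different seed, different forest
  f3 <- fit_learner(learner_spec("st_rf", seed = 2L, ntree = 30), tab1)
  expect_false(isTRUE(all.equal(predict(f1, tab1), predict(f3, tab1))))
})

test_that("mt_rf with uninformative taxonomy stays near st_rf", {
  # identical response surfaces; taxonomy columns carry no signal
  w <- linear_world(n_species = 4L, n_chem = 50L,
                    alphas = rep(1, 4), noise = 0.3, seed = 31L)
  tax <- make_taxonomy(sprintf("sp%02d", 1:4),
                       class_name = c("c1", "c1", "c2", "c2"),
                       phylum_name = "p1")
  train_chem <- w$chemicals$chemical_id[1:40]
  tr <- w$records[w$records$chemical_id %in% train_chem, ]
  te <- w$records[!w$records$chemical_id %in% train_chem, ]
  st_tr <- build_model_table(tr, w$chemicals, tax, "single_task")
  st_te <- build_model_table(te, w$chemicals, tax, "single_task",
                             schema = st_tr$schema)
  mt_tr <- build_model_table(tr, w$chemicals, tax, "multi_task")
  mt_te <- build_model_table(te, w$chemicals, tax, "multi_task",
                             schema = mt_tr$schema)
  e_st <- rmse(st_te$y, predict(fit_learner(
    learner_spec("st_rf", ntree = 100), st_tr), st_te))
  e_mt <- rmse(mt_te$y, predict(fit_learner(
    learner_spec("mt_rf", ntree = 100), mt_tr), mt_te))
  expect_lt(e_mt, 2 * e_st)
})

test_that("stacked ensemble is affine in its base predictions", {
  w <- linear_world(n_species = 3L, n_chem = 40L, noise = 0.2)
  tab <- small_tables(w, "multi_task")
  fit <- fit_learner(learner_spec("mt_stack", ntree = 40, nrounds = 40,
                                  k_folds = 3), tab)
  m <- fit$model
  base_preds <- vapply(m$bases, function(b) predict(b, tab$x),
                       numeric(nrow(tab$x)))
  expect_equal(predict(fit, tab),
               drop(m$meta[1] + base_preds %*% m$meta[-1]),
               tolerance = 1e-10)
  # on a clean linear surface the stack beats the pooled mean comfortably
  expect_lt(rmse(tab$y, predict(fit, tab)),
            rmse(tab$y, rep(mean(tab$y), length(tab$y))))
})

test_that("schema fingerprint mismatches are refused", {
  w <- linear_world()
  tab <- small_tables(w)
  fit <- fit_learner(learner_spec("st_mean"), tab)
  other <- tab
  other$x <- other$x[, rev(colnames(other$x)), drop = FALSE]
  expect_error(predict(fit, other), "schema mismatch")
  expect_error(fit_learner(learner_spec("mt_rf"), tab), "requires")
})

test_that("neural networks honour their structural contracts", {
  w <- linear_world(n_species = 3L, n_chem = 40L, noise = 0.1)
  tab <- small_tables(w)
  mt_tab <- small_tables(w, "multi_task")

  # multitarget output width equals the number of training species
  fit <- fit_learner(learner_spec("multitarget_nn", hidden = c(8, 8),
                                  epochs = 5, val_frac = 0), tab)
  expect_equal(length(fit$model$species), 3L)
  expect_equal(ncol(fit$model$net$W[[length(fit$model$net$W)]]), 3L)
  # unseen species has no head
  expect_false(can_predict(fit, "ghost"))

  # zero-epoch training: predictions at initialization, finite loss
  f0 <- fit_learner(learner_spec("nn_one_output", hidden = c(8, 8),
                                 epochs = 0, val_frac = 0), mt_tab)
  p0 <- predict(f0, mt_tab)
  expect_true(all(is.finite(p0)))
  init <- nn_new(ncol(mt_tab$x), 1L, hidden = c(8, 8),
                 seed = f0$spec$seed)
  expect_identical(lapply(f0$model$net$W, dim),
                   lapply(init$W, dim))
  expect_equal(f0$model$net$W, init$W)  # untouched parameters

  # trained one-output net beats the pooled mean on held-out rows
  tr_chem <- w$chemicals$chemical_id[1:32]
  tr <- w$records[w$records$chemical_id %in% tr_chem, ]
  te <- w$records[!w$records$chemical_id %in% tr_chem, ]
  mt_tr <- build_model_table(tr, w$chemicals, w$taxonomy, "multi_task")
  mt_te <- build_model_table(te, w$chemicals, w$taxonomy, "multi_task",
                             schema = mt_tr$schema)
  nn <- fit_learner(learner_spec("nn_one_output", hidden = c(32, 32),
                                 epochs = 150, val_frac = 0), mt_tr)
  mean_fit <- fit_learner(learner_spec("mt_mean"), mt_tr)
  expect_lt(rmse(mt_te$y, predict(nn, mt_te)),
            rmse(mt_te$y, predict(mean_fit, mt_te)))
})

test_that("fine-tuning trains the head only", {
  # nn_train freeze contract: non-head layers bit-identical
  net <- nn_new(4, 1, hidden = c(6, 6), seed = 2)
  X <- matrix(rnorm(80), 20, 4)
  y <- rnorm(20)
  tuned <- nn_train(net, X, y, epochs = 10, batch = 10,
                    train_layers = 3L, seed = 3)
  expect_identical(tuned$W[[1]], net$W[[1]])
  expect_identical(tuned$W[[2]], net$W[[2]])
  expect_identical(tuned$b[[1]], net$b[[1]])
  expect_false(identical(tuned$W[[3]], net$W[[3]]))

  # zero fine-tune epochs reproduce the pretrained network exactly
  w <- linear_world(n_species = 3L, n_chem = 30L, noise = 0.1)
  mt_tab <- small_tables(w, "multi_task")
  ft0 <- fit_learner(learner_spec("finetune_top", hidden = c(8, 8),
                                  epochs = 10, ft_epochs = 0,
                                  val_frac = 0), mt_tab)
  base_pred <- aquamtl:::.predict_nn_shared(ft0$model, mt_tab)
  expect_equal(predict(ft0, mt_tab), base_pred, tolerance = 1e-12)

  # species offset from the global surface is recovered by head tuning
  w2 <- linear_world(n_species = 4L, n_chem = 40L,
                     alphas = c(1, 1, 1, 3), noise = 0.05, seed = 17L)
  mt2 <- build_model_table(w2$records, w2$chemicals, w2$taxonomy,
                           "multi_task")
  ft <- fit_learner(learner_spec("finetune_top", hidden = c(16, 16),
                                 epochs = 60, ft_epochs = 60,
                                 val_frac = 0), mt2)
  idx <- mt2$species == "sp04"
  sub <- aquamtl:::.table_subset(mt2, which(idx))
  pre <- rmse(sub$y, aquamtl:::.predict_nn_shared(ft$model, sub))
  post <- rmse(sub$y, predict(ft, sub))
  expect_lte(post, pre + 1e-8)
})
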