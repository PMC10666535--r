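#' Chemicals-disjoint train/test split
#'
#' Partitions the chemical set uniformly at random; every assay of a
#' chemical lands on that chemical's side, so test compounds are never
#' seen during training in any form.
#'
#' @param chemicals character vector of chemical ids (duplicates allowed;
#'   the unique set is split).
#' @param test_fraction fraction of chemicals for the test side (0 < f < 1).
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `train_chemicals`,
#'   `test_chemicals`, `seed`.
#' @export
split_by_chemicals <- function(chemicals, test_fraction, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  chems <- sort(unique(chemicals))
  if (length(chems) < 2L) stop("need at least 2 chemicals to split")
  n_test <- max(1L, round(test_fraction * length(chems)))
  withr::with_seed(as.integer(seed), {
    test <- sort(sample(chems, n_test))
  })
  structure(list(train_chemicals = setdiff(chems, test),
                 test_chemicals = test, seed = as.integer(seed)),
            class = "split_plan")
}

#' Repeated k-fold internal cross-validation plan over chemicals
#'
#' Partitions the training chemicals into `k` disjoint subfolds of sizes
#' differing by at most one, repeated `repetitions` times with different
#' partitions — `k * repetitions` split plans in total (the canonical
#' 5 x 3 = 15 internal estimates).
#'
#' @param train_chemicals character vector of training chemical ids.
#' @param k number of subfolds (>= 2).
#' @param repetitions number of independent partitions.
#' @param seed integer seed.
#' @return list of `split_plan`s with attributes `fold` and `repetition`
#'   stored in each plan.
#' @export
internal_cv_plan <- function(train_chemicals, k = 5L, repetitions = 3L,
                             seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  chems <- sort(unique(train_chemicals))
  if (length(chems) < k) stop("fewer chemicals than subfolds")
  plans <- list()
  for (r in seq_len(repetitions)) {
    withr::with_seed(.subseed(seed, r), {
      fold_of <- sample(rep_len(seq_len(k), length(chems)))
    })
    for (f in seq_len(k)) {
      plan <- structure(
        list(train_chemicals = chems[fold_of != f],
             test_chemicals = chems[fold_of == f],
             seed = as.integer(seed)),
        class = "split_plan")
      plan$fold <- f
      plan$repetition <- r
      plans[[length(plans) + 1L]] <- plan
    }
  }
  plans
}

#' Root mean squared error
#'
#' @param y true values.
#' @param y_hat predicted values (same length, >= 1).
#' @return `sqrt(mean((y_hat - y)^2))`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 1L) stop("empty input")
  sqrt(mean((y_hat - y)^2))
}

#' Grouped RMSE aggregation
#'
#' Computes one RMSE per group (species, chemical or fold) and summarizes
#' with the *unweighted* mean and median over groups — so a group with one
#' prediction weighs exactly as much as a group with a thousand, which is
#' precisely why species- and chemical-grouped summaries differ on
#' unbalanced data.
#'
#' @param predictions data.frame with columns `y`, `y_hat` and the
#'   grouping column.
#' @param by name of the grouping column (e.g. `"species"`,
#'   `"chemical"`, `"fold"`).
#' @return list with `groups` (data.frame: group, n, rmse), `mean`,
#'   `median`.
#' @export
aggregate_rmse <- function(predictions, by = "species") {
  .stopifnot_cols(predictions, c("y", "y_hat", by), "predictions")
  if (nrow(predictions) == 0L) stop("no predictions to aggregate")
  g <- factor(predictions[[by]])
  per <- vapply(split(seq_len(nrow(predictions)), g), function(idx)
    rmse(predictions$y[idx], predictions$y_hat[idx]), numeric(1))
  groups <- data.frame(group = levels(g),
                       n = as.integer(table(g)),
                       rmse = unname(per), stringsAsFactors = FALSE)
  list(groups = groups, mean = mean(per), median = median(per))
}

#' Friedman test with Nemenyi post-hoc critical difference
#'
#' Compares k algorithms over N datasets (groups) of errors following
#' Demsar's protocol: average ranks per dataset (ties share the mean
#' rank), Friedman chi-square
#' `chi2_F = 12N / (k(k+1)) * (sum R_j^2 - k(k+1)^2 / 4)` on the mean
#' ranks, the Iman–Davenport correction
#' `F_F = (N-1) chi2_F / (N(k-1) - chi2_F)` tested against
#' F(k-1, (k-1)(N-1)), and the Nemenyi critical difference
#' `CD = q_alpha * sqrt(k(k+1) / (6N))` with `q_alpha` the Studentized
#' range quantile at infinite df divided by sqrt(2).
#'
#' @param errors numeric matrix, rows = datasets/groups, columns =
#'   algorithms (no missing cells); lower is better.
#' @param alpha significance level for the critical difference (0.05 or
#'   0.10 are customary).
#' @return list with `mean_ranks`, `chi_sq`, `chi_sq_p`, `f_stat`,
#'   `p_value` (Iman–Davenport), `cd`, and the logical `significant`
#'   pairwise matrix (`|rank diff| > CD`).
#' @export
friedman_nemenyi <- function(errors, alpha = 0.05) {
  errors <- as.matrix(errors)
  N <- nrow(errors); k <- ncol(errors)
  if (N < 2L || k < 2L) stop("need >= 2 algorithms and >= 2 datasets")
  if (anyNA(errors)) stop("missing cells are not allowed")
  ranks <- t(apply(errors, 1, rank))  # average ranks on ties
  R <- colMeans(ranks)
  chi_sq <- 12 * N / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
  chi_sq <- max(chi_sq, 0)
  chi_sq_p <- pchisq(chi_sq, df = k - 1, lower.tail = FALSE)
  denom <- N * (k - 1) - chi_sq
  if (denom <= 1e-12) {
    f_stat <- Inf; p_value <- 0
  } else {
    f_stat <- (N - 1) * chi_sq / denom
    p_value <- pf(f_stat, k - 1, (k - 1) * (N - 1), lower.tail = FALSE)
  }
  if (chi_sq == 0) p_value <- 1
  cd <- qtukey(1 - alpha, k, Inf) / sqrt(2) * sqrt(k * (k + 1) / (6 * N))
  diff <- abs(outer(R, R, "-"))
  sig <- diff > cd
  diag(sig) <- FALSE
  nm <- colnames(errors) %||% paste0("alg", seq_len(k))
  names(R) <- nm
  dimnames(sig) <- list(nm, nm)
  list(mean_ranks = R, chi_sq = chi_sq, chi_sq_p = chi_sq_p,
       f_stat = f_stat, p_value = p_value, cd = cd, significant = sig)
}

# ---- fit/predict harness with leakage audit ------------------------------

#' Assert that a training table is free of test chemicals
#'
#' Instrumented leakage audit: every experiment path calls this on each
#' training table before any fit, imputation or feature-selection step, so
#' a test chemical can never influence a fitted statistic.
#'
#' @param train_chemicals chemicals present in a training table.
#' @param test_chemicals the split's held-out chemicals.
#' @return `TRUE` invisibly; stops on any overlap.
#' @export
assert_no_leakage <- function(train_chemicals, test_chemicals) {
  bad <- intersect(unique(train_chemicals), test_chemicals)
  if (length(bad))
    stop(sprintf("leakage audit failed: %d test chemical(s) in training data (e.g. %s)",
                 length(bad), bad[1]))
  invisible(TRUE)
}

# Build single- and multi-task tables for a record split, fit every spec,
# and return long-format predictions on the test rows.  Schemas (median
# imputation, constant-column drop, taxonomy levels) are fitted on the
# training records and re-applied to the test records.
.fit_predict_all <- function(specs, train_records, test_records, chemicals,
                             taxonomy, test_chemicals = NULL) {
  if (is.null(test_chemicals)) test_chemicals <- unique(test_records$chemical_id)
  assert_no_leakage(train_records$chemical_id, test_chemicals)
  modes <- unique(vapply(specs, function(s) learner_mode(s$family),
                         character(1)))
  train_tab <- list(); test_tab <- list()
  for (m in modes) {
    train_tab[[m]] <- build_model_table(train_records, chemicals, taxonomy,
                                        mode = m)
    test_tab[[m]] <- build_model_table(test_records, chemicals, taxonomy,
                                       mode = m,
                                       schema = train_tab[[m]]$schema)
  }
  out <- list()
  for (spec in specs) {
    m <- learner_mode(spec$family)
    fit <- fit_learner(spec, train_tab[[m]])
    tt <- test_tab[[m]]
    ok <- can_predict(fit, tt$species)
    pred <- rep(NA_real_, length(ok))
    if (any(ok)) {
      sub <- .table_subset(tt, which(ok))
      pred[ok] <- predict(fit, sub)
    }
    out[[length(out) + 1L]] <- data.frame(
      learner = spec$family, species = tt$species, chemical = tt$chemical,
      duration = tt$duration, y = tt$y, y_hat = pred, covered = ok,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fit learners on a training split and score a test split
#'
#' Convenience wrapper around the internal harness: builds tables in the
#' modes the families need (schemas fitted on training records only,
#' leakage-audited), fits every spec and returns long-format test
#' predictions with per-learner coverage.
#'
#' @param specs list of [learner_spec()]s.
#' @param records cleaned assay records ([preprocess_assays()]).
#' @param split a [split_by_chemicals()] plan.
#' @param chemicals,taxonomy feature and taxonomy tables.
#' @return data.frame (learner, species, chemical, duration, y, y_hat,
#'   covered).
#' @export
evaluate_split <- function(specs, records, split, chemicals, taxonomy) {
  stopifnot(inherits(split, "split_plan"))
  train <- records[records$chemical_id %in% split$train_chemicals, ,
                   drop = FALSE]
  test <- records[records$chemical_id %in% split$test_chemicals, ,
                  drop = FALSE]
  if (nrow(train) == 0L || nrow(test) == 0L)
    stop("split leaves an empty train or test side")
  # score only species present in training (coverage is reported per
  # learner; families differ in what they can do with unseen species)
  test <- test[test$species_id %in% unique(train$species_id), ,
               drop = FALSE]
  .fit_predict_all(specs, train, test, chemicals, taxonomy,
                   split$test_chemicals)
}

#' Run the repeated internal cross-validation harness
#'
#' Executes every (repetition, fold) plan of [internal_cv_plan()] for every
#' learner and returns one performance estimate per learner per plan —
#' with the default `k = 5`, `repetitions = 3` that is 15 estimates per
#' learner.
#'
#' @inheritParams evaluate_split
#' @param k,repetitions,seed passed to [internal_cv_plan()].
#' @param by grouping for the per-plan RMSE summary (`"fold"` computes the
#'   plain RMSE over all test rows of the fold; `"species"`/`"chemical"`
#'   average group RMSEs).
#' @return data.frame (learner, repetition, fold, n_test, rmse).
#' @export
run_internal_validation <- function(specs, records, chemicals, taxonomy,
                                    k = 5L, repetitions = 3L, seed = 1L,
                                    by = "fold") {
  plans <- internal_cv_plan(unique(records$chemical_id), k = k,
                            repetitions = repetitions, seed = seed)
  out <- list()
  for (plan in plans) {
    preds <- evaluate_split(specs, records, plan, chemicals, taxonomy)
    preds <- preds[preds$covered, , drop = FALSE]
    for (fam in unique(preds$learner)) {
      p <- preds[preds$learner == fam, , drop = FALSE]
      est <- if (by == "fold") rmse(p$y, p$y_hat)
             else aggregate_rmse(p, by = by)$mean
      out[[length(out) + 1L]] <- data.frame(
        learner = fam, repetition = plan$repetition, fold = plan$fold,
        n_test = nrow(p), rmse = est, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Small grid-search harness over chemicals-disjoint internal folds
#'
#' Stand-in for a full hyperparameter-optimization protocol: evaluates
#' each hyperparameter combination with a k-fold chemicals-disjoint
#' internal validation and returns the spec with the lowest mean RMSE.
#'
#' @param family learner family.
#' @param grid named list of hyperparameter value vectors (full factorial).
#' @param records,chemicals,taxonomy data as in [evaluate_split()].
#' @param k internal folds.
#' @param seed seed for folds and fits.
#' @return list with `best` ([learner_spec()]) and `results` data.frame.
#' @export
tune_learner <- function(family, grid, records, chemicals, taxonomy,
                         k = 3L, seed = 1L) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  if (nrow(combos) == 0L) stop("empty grid")
  plans <- internal_cv_plan(unique(records$chemical_id), k = k,
                            repetitions = 1L, seed = seed)
  score <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    spec <- do.call(learner_spec,
                    c(list(family = family, seed = seed),
                      as.list(combos[i, , drop = FALSE])))
    ests <- vapply(plans, function(plan) {
      preds <- evaluate_split(list(spec), records, plan, chemicals,
                              taxonomy)
      preds <- preds[preds$covered, , drop = FALSE]
      rmse(preds$y, preds$y_hat)
    }, numeric(1))
    score[i] <- mean(ests)
  }
  best_i <- which.min(score)
  best <- do.call(learner_spec,
                  c(list(family = family, seed = seed),
                    as.list(combos[best_i, , drop = FALSE])))
  list(best = best,
       results = cbind(combos, mean_rmse = score))
}
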