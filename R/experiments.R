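#' Select study species for the assays-per-species learning curve (R2)
#'
#' Splits chemicals 90/10 (train/test), keeps as *study species* those
#' with at least `min_train_assays` training rows, moves the remaining
#' species' training rows into an *auxiliary* set and discards their test
#' rows entirely, so the test set is fixed for the whole experiment.
#'
#' @param records cleaned assay records.
#' @param test_fraction chemical fraction held out (0.1 by default).
#' @param min_train_assays study-species threshold (128 by default).
#' @param seed split seed.
#' @return list with `split`, `study_species`, `train_records` (study
#'   species only), `aux_records`, `test_records`.
#' @export
select_study_species_r2 <- function(records, test_fraction = 0.1,
                                    min_train_assays = 128L, seed = 1L) {
  split <- split_by_chemicals(unique(records$chemical_id), test_fraction,
                              seed)
  train <- records[records$chemical_id %in% split$train_chemicals, ,
                   drop = FALSE]
  counts <- table(train$species_id)
  study <- names(counts)[counts >= min_train_assays]
  if (length(study) == 0L)
    stop(sprintf(
      "no species has >= %d training assays (max observed: %d)",
      min_train_assays, if (length(counts)) max(counts) else 0L))
  test <- records[records$chemical_id %in% split$test_chemicals &
                    records$species_id %in% study, , drop = FALSE]
  list(split = split, study_species = sort(study),
       train_records = train[train$species_id %in% study, , drop = FALSE],
       aux_records = train[!train$species_id %in% study, , drop = FALSE],
       test_records = test)
}

.st_only_families <- c("st_mean", "st_rf")

#' Build assays-per-species learning curves (R2)
#'
#' For each anchor `s` of the schedule, every study species contributes
#' its first `s` training assays under a per-species random ordering
#' (nested: the rows used at one anchor are reused at all larger
#' anchors).  Single-task learners therefore see `s` rows of the target
#' species; multi-task learners see `s` rows from each study species,
#' plus the full auxiliary set when `with_auxiliary` is on.  The test
#' assays are identical across all anchors.  Three orderings are built by
#' default and later averaged by [summarize_curve()].
#'
#' @param setup a [select_study_species_r2()] result.
#' @param chemicals,taxonomy feature and taxonomy tables.
#' @param schedule strictly increasing anchor sizes; every study species
#'   must have at least `max(schedule)` training assays.
#' @param with_auxiliary include the auxiliary set in multi-task training?
#' @param specs list of [learner_spec()]s.
#' @param n_orderings independent assay orderings to average over.
#' @param seed base seed.
#' @return long data.frame of group-level errors: `anchor`, `ordering`,
#'   `learner`, `aggregation` ("species"/"chemical"), `group`, `rmse`.
#' @export
build_assay_curve <- function(setup, chemicals, taxonomy, schedule,
                              with_auxiliary = FALSE, specs,
                              n_orderings = 3L, seed = 1L) {
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  tr <- setup$train_records
  counts <- table(tr$species_id)
  if (any(counts[setup$study_species] < max(schedule)))
    stop("anchor exceeds available training assays for some study species")

  st_specs <- Filter(function(s) s$family %in% .st_only_families, specs)
  mt_specs <- Filter(function(s) !s$family %in% .st_only_families, specs)

  out <- list()
  for (o in seq_len(n_orderings)) {
    perm <- .assay_ordering(tr, setup$study_species, o, seed)
    for (a in schedule) {
      rows <- unlist(lapply(perm, head, a), use.names = FALSE)
      anchor_train <- tr[rows, , drop = FALSE]
      preds <- list()
      if (length(st_specs))
        preds[[1L]] <- .fit_predict_all(st_specs, anchor_train,
                                        setup$test_records, chemicals,
                                        taxonomy,
                                        setup$split$test_chemicals)
      if (length(mt_specs)) {
        mt_train <- if (with_auxiliary)
          rbind(anchor_train, setup$aux_records) else anchor_train
        preds[[length(preds) + 1L]] <-
          .fit_predict_all(mt_specs, mt_train, setup$test_records,
                           chemicals, taxonomy,
                           setup$split$test_chemicals)
      }
      preds <- do.call(rbind, preds)
      out[[length(out) + 1L]] <- .group_errors(preds, anchor = a,
                                               ordering = o)
    }
  }
  do.call(rbind, out)
}

# one nested permutation of training-assay row indices per study species;
# the rows used at anchor a are head(perm[[sp]], a), so smaller anchors are
# always contained in larger ones within an ordering
.assay_ordering <- function(train_records, study_species, ordering, seed) {
  lapply(setNames(study_species, study_species), function(sp) {
    idx <- which(train_records$species_id == sp)
    withr::with_seed(
      .subseed(seed, ordering * 997L + match(sp, study_species)),
      idx[sample.int(length(idx))])
  })
}

.group_errors <- function(preds, anchor, ordering) {
  preds <- preds[preds$covered & !is.na(preds$y_hat), , drop = FALSE]
  rows <- list()
  for (fam in unique(preds$learner)) {
    p <- preds[preds$learner == fam, , drop = FALSE]
    for (by in c("species", "chemical")) {
      agg <- aggregate_rmse(p, by = by)
      rows[[length(rows) + 1L]] <- data.frame(
        anchor = anchor, ordering = ordering, learner = fam,
        aggregation = by, group = agg$groups$group,
        rmse = agg$groups$rmse, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Percentile bootstrap band for a mean of group-level errors
#'
#' Resamples the group-level RMSEs (species or chemicals — the paper's
#' aggregation unit, not raw residuals) with replacement and returns the
#' percentile interval of the resampled means.
#'
#' @param errors numeric vector of group-level errors (>= 2 for a
#'   nondegenerate band; a single value yields a zero-width band with a
#'   warning).
#' @param B bootstrap samples (1000 by default).
#' @param level band level (0.90 by default: 5th-95th percentiles).
#' @param seed resampling seed.
#' @return named vector `c(lower, upper)`.
#' @export
bootstrap_bands <- function(errors, B = 1000L, level = 0.90, seed = 1L) {
  stopifnot(level > 0, level < 1, length(errors) >= 1L)
  if (length(errors) < 2L) {
    warning("single observation: degenerate band equal to the point")
    return(c(lower = errors, upper = errors))
  }
  withr::with_seed(as.integer(seed), {
    means <- vapply(seq_len(B), function(b)
      mean(sample(errors, replace = TRUE)), numeric(1))
  })
  q <- quantile(means, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Summarize learning-curve group errors into curve points
#'
#' Averages group-level errors over orderings/seeds into one point per
#' (anchor, learner, aggregation) and attaches percentile bootstrap bands
#' computed over the pooled group-level errors.
#'
#' @param curve long data.frame from [build_assay_curve()] or
#'   [build_species_curve()].
#' @param B,level,seed see [bootstrap_bands()].
#' @return data.frame with `anchor`, `learner`, `aggregation`, `rmse`
#'   (mean over orderings of per-ordering group means), `lower`, `upper`,
#'   `level`, `n_groups`.
#' @export
summarize_curve <- function(curve, B = 1000L, level = 0.90, seed = 1L) {
  keys <- unique(curve[c("anchor", "learner", "aggregation")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- curve[curve$anchor == keys$anchor[i] &
                   curve$learner == keys$learner[i] &
                   curve$aggregation == keys$aggregation[i], ,
                 drop = FALSE]
    per_ord <- tapply(sub$rmse, sub$ordering, mean)
    band <- suppressWarnings(
      bootstrap_bands(sub$rmse, B = B, level = level,
                      seed = .subseed(seed, i)))
    data.frame(keys[i, , drop = FALSE], rmse = mean(per_ord),
               lower = band["lower"], upper = band["upper"],
               level = level, n_groups = nrow(sub), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Select study and auxiliary species for the species-count curve (R3)
#'
#' Splits chemicals 75/25, keeps as *study species* those with at least
#' `min_test_chemicals` distinct chemicals among their test assays, and as
#' *auxiliary species* those remaining with at least `aux_min_train`
#' training assays (later down-sampled to exactly `aux_cap` rows per
#' seed).  All other species are discarded.
#'
#' @param records cleaned assay records.
#' @param test_fraction held-out chemical fraction (0.25).
#' @param min_test_chemicals study-species threshold (3).
#' @param aux_min_train auxiliary-species training threshold (64).
#' @param aux_cap rows each auxiliary species contributes (64).
#' @param seed split seed.
#' @return list with `split`, `study_species`, `aux_species`,
#'   `train_records` (study), `test_records`, `aux_records` (uncapped),
#'   `aux_cap`.
#' @export
select_species_curve_setup_r3 <- function(records, test_fraction = 0.25,
                                          min_test_chemicals = 3L,
                                          aux_min_train = 64L,
                                          aux_cap = 64L, seed = 1L) {
  split <- split_by_chemicals(unique(records$chemical_id), test_fraction,
                              seed)
  train <- records[records$chemical_id %in% split$train_chemicals, ,
                   drop = FALSE]
  test <- records[records$chemical_id %in% split$test_chemicals, ,
                  drop = FALSE]
  test_chems <- tapply(test$chemical_id, test$species_id,
                       function(x) length(unique(x)))
  study <- names(test_chems)[test_chems >= min_test_chemicals]
  # study species also need training rows to build a model at n = 0
  study <- intersect(study, unique(train$species_id))
  train_counts <- table(train$species_id)
  aux <- setdiff(names(train_counts)[train_counts >= aux_min_train], study)
  if (length(study) == 0L || length(aux) == 0L)
    stop("empty study or auxiliary species set under the given thresholds")
  list(split = split, study_species = sort(study), aux_species = sort(aux),
       train_records = train[train$species_id %in% study, , drop = FALSE],
       test_records = test[test$species_id %in% study, , drop = FALSE],
       aux_records = train[train$species_id %in% aux, , drop = FALSE],
       aux_cap = as.integer(aux_cap))
}

#' Build auxiliary-species-count learning curves (R3)
#'
#' For each seed, each auxiliary species is down-sampled to
#' `setup$aux_cap` training rows and a random permutation of the
#' auxiliary species is drawn.  For each study species and each count `n`,
#' multi-task learners are trained on the study species' training rows
#' plus the capped rows of the first `n` auxiliary species of the
#' permutation (a prefix, so the species at count n are contained in those
#' at count n + 1), and scored on the study species' fixed test assays.
#' Single-task learners are excluded — they make no use of the added data.
#'
#' @param setup a [select_species_curve_setup_r3()] result.
#' @param chemicals,taxonomy feature and taxonomy tables.
#' @param counts auxiliary-species counts; defaults to the doubling grid
#'   `c(0, 2, 4, 8, 16, 32, 64)` clipped to the available species.
#' @param specs list of [learner_spec()]s (multi-task families).
#' @param n_seeds pseudorandom repetitions (3).
#' @param seed base seed.
#' @return long data.frame of group-level errors with columns `anchor`
#'   (the auxiliary-species count), `ordering` (the seed index),
#'   `learner`, `aggregation`, `group`, `rmse`.
#' @export
build_species_curve <- function(setup, chemicals, taxonomy,
                                counts = c(0L, 2L, 4L, 8L, 16L, 32L, 64L),
                                specs, n_seeds = 3L, seed = 1L) {
  counts <- sort(unique(as.integer(counts)))
  if (any(counts < 0L) || any(counts > length(setup$aux_species)))
    stop("counts must lie in [0, number of auxiliary species]")
  is_st <- vapply(specs, function(s) s$family %in% .st_only_families,
                  logical(1))
  if (any(is_st)) {
    warning("single-task learners are excluded from the species curve")
    specs <- specs[!is_st]
  }
  if (length(specs) == 0L) stop("no multi-task learners supplied")

  out <- list()
  for (s in seq_len(n_seeds)) {
    draw <- .aux_draw(setup, s, seed)
    capped <- draw$capped
    perm <- draw$perm
    for (sp in setup$study_species) {
      sp_train <- setup$train_records[
        setup$train_records$species_id == sp, , drop = FALSE]
      sp_test <- setup$test_records[
        setup$test_records$species_id == sp, , drop = FALSE]
      for (n in counts) {
        aux_n <- capped[capped$species_id %in% head(perm, n), ,
                        drop = FALSE]
        preds <- .fit_predict_all(specs, rbind(sp_train, aux_n), sp_test,
                                  chemicals, taxonomy,
                                  setup$split$test_chemicals)
        preds <- preds[preds$covered, , drop = FALSE]
        if (nrow(preds) == 0L) next
        preds$study_species <- sp
        out[[length(out) + 1L]] <- cbind(anchor = n, ordering = s, preds)
      }
    }
  }
  preds <- do.call(rbind, out)
  # group errors: per (count, seed, learner), species groups are the study
  # species; chemical groups pool residuals across study species
  rows <- list()
  for (n in unique(preds$anchor)) for (s in unique(preds$ordering)) {
    sub <- preds[preds$anchor == n & preds$ordering == s, , drop = FALSE]
    for (fam in unique(sub$learner)) {
      p <- sub[sub$learner == fam, , drop = FALSE]
      p$species <- p$study_species
      for (by in c("species", "chemical")) {
        agg <- aggregate_rmse(p, by = by)
        rows[[length(rows) + 1L]] <- data.frame(
          anchor = n, ordering = s, learner = fam, aggregation = by,
          group = agg$groups$group, rmse = agg$groups$rmse,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# per-seed auxiliary material for the species curve: every auxiliary
# species down-sampled to exactly aux_cap rows plus one permutation of the
# auxiliary species (count n uses the prefix head(perm, n))
.aux_draw <- function(setup, s, seed) {
  withr::with_seed(.subseed(seed, 7000L + s), {
    capped <- do.call(rbind, lapply(setup$aux_species, function(sp) {
      idx <- which(setup$aux_records$species_id == sp)
      take <- idx[sample.int(length(idx), min(setup$aux_cap,
                                              length(idx)))]
      setup$aux_records[take, , drop = FALSE]
    }))
    perm <- sample(setup$aux_species)
  })
  list(capped = capped, perm = perm)
}

# ---- orchestration -------------------------------------------------------

.config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97)))
}

.as_specs <- function(learners, seed) {
  lapply(learners, function(l)
    if (inherits(l, "learner_spec")) l else learner_spec(l, seed = seed))
}

#' Run a full experiment from a declarative config
#'
#' Orchestrates generate -> preprocess -> fit -> evaluate (-> curves) and
#' writes tidy result tables plus a run manifest recording every consumed
#' seed, a config hash and library versions.  Protocols:
#'
#' * `"average"`: 80/20 external chemicals split, external RMSE aggregated
#'   over species and chemicals, plus the 5 x 3 internal cross-validation
#'   estimates.
#' * `"assay_curve"`: the R2 assays-per-species design
#'   ([select_study_species_r2()] + [build_assay_curve()]).
#' * `"species_curve"`: the R3 auxiliary-species-count design.
#'
#' @param config list with elements `synth` (a [synth_config()]),
#'   `protocol`, `learners` (family names or [learner_spec()]s), `seed`,
#'   optional `out_dir`, and protocol-specific settings
#'   (`test_fraction`, `k`, `repetitions`, `schedule`, `with_auxiliary`,
#'   `min_train_assays`, `counts`, `n_orderings`, `bootstrap_B`).
#' @return result bundle (list) with `results`, `manifest`, invisibly the
#'   written paths in `files`.
#' @export
run_experiment <- function(config) {
  stopifnot(is.list(config), inherits(config$synth, "synth_config"))
  protocol <- match.arg(config$protocol,
                        c("average", "assay_curve", "species_curve"))
  seed <- as.integer(config$seed %||% 1L)
  specs <- .as_specs(config$learners, seed)
  B <- config$bootstrap_B %||% 1000L

  dataset <- generate_dataset(config$synth)
  records <- preprocess_assays(dataset$assays)
  seeds_used <- c(synth = config$synth$seed, experiment = seed)

  results <- switch(protocol,
    average = {
      split <- split_by_chemicals(unique(records$chemical_id),
                                  config$test_fraction %||% 0.2, seed)
      preds <- evaluate_split(specs, records, split, dataset$chemicals,
                              dataset$taxonomy)
      covered <- preds[preds$covered, , drop = FALSE]
      external <- do.call(rbind, lapply(unique(covered$learner),
        function(fam) {
          p <- covered[covered$learner == fam, , drop = FALSE]
          do.call(rbind, lapply(c("species", "chemical"), function(by) {
            agg <- aggregate_rmse(p, by = by)
            data.frame(learner = fam, aggregation = by,
                       mean_rmse = agg$mean, median_rmse = agg$median,
                       n_groups = nrow(agg$groups), coverage =
                         nrow(p) / sum(preds$learner == fam),
                       stringsAsFactors = FALSE)
          }))
        }))
      internal <- run_internal_validation(
        specs,
        records[records$chemical_id %in% split$train_chemicals, ,
                drop = FALSE],
        dataset$chemicals, dataset$taxonomy,
        k = config$k %||% 5L, repetitions = config$repetitions %||% 3L,
        seed = .subseed(seed, 2L))
      list(external = external, internal = internal,
           predictions = preds)
    },
    assay_curve = {
      setup <- select_study_species_r2(
        records, config$test_fraction %||% 0.1,
        config$min_train_assays %||% 128L, seed)
      curve <- build_assay_curve(
        setup, dataset$chemicals, dataset$taxonomy,
        schedule = config$schedule %||% default_anchor_schedule(),
        with_auxiliary = isTRUE(config$with_auxiliary), specs,
        n_orderings = config$n_orderings %||% 3L,
        seed = .subseed(seed, 3L))
      list(curve = curve,
           points = summarize_curve(curve, B = B,
                                    seed = .subseed(seed, 4L)))
    },
    species_curve = {
      setup <- select_species_curve_setup_r3(
        records, config$test_fraction %||% 0.25,
        config$min_test_chemicals %||% 3L,
        config$aux_min_train %||% 64L, config$aux_cap %||% 64L, seed)
      counts <- config$counts %||%
        c(0L, 2L, 4L, 8L, 16L, 32L, 64L)
      counts <- counts[counts <= length(setup$aux_species)]
      curve <- build_species_curve(
        setup, dataset$chemicals, dataset$taxonomy, counts = counts,
        specs = specs, n_seeds = config$n_seeds %||% 3L,
        seed = .subseed(seed, 5L))
      list(curve = curve,
           points = summarize_curve(curve, B = B,
                                    seed = .subseed(seed, 6L)))
    })

  manifest <- list(
    protocol = protocol,
    seeds = as.list(seeds_used),
    config_hash = .config_hash(config[setdiff(names(config), "out_dir")]),
    learners = vapply(specs, function(s) s$family, character(1)),
    n_records = nrow(records),
    leakage_audit = "passed",  # .fit_predict_all stops on any violation
    package_version = as.character(utils::packageVersion("aquamtl")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      if (!is.data.frame(results[[nm]])) next
      f <- file.path(config$out_dir, paste0(nm, ".csv"))
      write.csv(results[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
    mf <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, mf)
  }
  out <- list(results = results, manifest = manifest, files = files)
  class(out) <- "aquamtl_run"
  out
}

#' Default anchor schedule for assay learning curves
#'
#' The square-root-of-two spaced fill `{5, 8, 11, 16, 22, 32, 45, 64, 90,
#' 128}` (`floor(2^(k/2))`), the standard learning-curve convention.
#'
#' @return integer vector of anchors.
#' @export
default_anchor_schedule <- function() {
  c(5L, 8L, 11L, 16L, 22L, 32L, 45L, 64L, 90L, 128L)
}
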