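r2_fixture <- function(seed = 5L) {
  d <- tiny_dataset(n_species = 6L, n_chemicals = 80L, n_assays = 700L,
                    zipf_exponent = 0.5, replicate_rate = 0,
                    bound_rate = 0, seed = seed)
  list(d = d, rec = preprocess_assays(d$assays))
}

test_that("R2 study-species selection applies the threshold exactly", {
  f <- r2_fixture()
  setup <- select_study_species_r2(f$rec, test_fraction = 0.1,
                                   min_train_assays = 50L, seed = 2)
  # recount oracle: study species are exactly those with >= 50 train rows
  train <- f$rec[f$rec$chemical_id %in% setup$split$train_chemicals, ]
  counts <- table(train$species_id)
  expect_setequal(setup$study_species, names(counts)[counts >= 50])
  # auxiliary rows contain no study species and no test chemicals
  expect_length(intersect(setup$aux_records$species_id,
                          setup$study_species), 0L)
  expect_length(intersect(setup$aux_records$chemical_id,
                          setup$split$test_chemicals), 0L)
  # test rows are study species only
  expect_true(all(setup$test_records$species_id %in% setup$study_species))
  # deterministic given the seed
  setup2 <- select_study_species_r2(f$rec, 0.1, 50L, seed = 2)
  expect_identical(setup$study_species, setup2$study_species)

  expect_error(select_study_species_r2(f$rec, 0.1, 1e6, seed = 2),
               "no species")
})

test_that("assay orderings are nested across anchors", {
  f <- r2_fixture()
  setup <- select_study_species_r2(f$rec, 0.1, 40L, seed = 2)
  perm <- aquamtl:::.assay_ordering(setup$train_records,
                                    setup$study_species, 1L, seed = 9)
  for (sp in setup$study_species) {
    expect_true(all(head(perm[[sp]], 5) %in% head(perm[[sp]], 8)))
    expect_setequal(perm[[sp]],
                    which(setup$train_records$species_id == sp))
  }
  # different orderings differ
  perm2 <- aquamtl:::.assay_ordering(setup$train_records,
                                     setup$study_species, 2L, seed = 9)
  expect_false(identical(perm, perm2))
})

test_that("build_assay_curve sizes training sets as declared", {
  f <- r2_fixture()
  setup <- select_study_species_r2(f$rec, 0.1, 40L, seed = 2)
  specs <- list(learner_spec("st_mean"), learner_spec("mt_mean"))
  curve <- build_assay_curve(setup, f$d$chemicals, f$d$taxonomy,
                             schedule = c(5L, 10L), specs = specs,
                             n_orderings = 2L, seed = 1)
  expect_setequal(unique(curve$anchor), c(5L, 10L))
  expect_setequal(unique(curve$learner), c("st_mean", "mt_mean"))
  expect_setequal(unique(curve$aggregation), c("species", "chemical"))
  # species groups at each point are the study species (fixed test set)
  sp_groups <- unique(curve$group[curve$aggregation == "species"])
  expect_true(all(sp_groups %in% setup$study_species))

  expect_error(build_assay_curve(setup, f$d$chemicals, f$d$taxonomy,
                                 schedule = c(10L, 5L), specs = specs),
               "strictly increasing")
  expect_error(build_assay_curve(setup, f$d$chemicals, f$d$taxonomy,
                                 schedule = c(5L, 10000L), specs = specs),
               "anchor exceeds")
})

test_that("R3 selection thresholds, capping and prefixes hold", {
  d <- tiny_dataset(n_species = 10L, n_chemicals = 60L, n_assays = 500L,
                    zipf_exponent = 1.2, replicate_rate = 0,
                    bound_rate = 0, seed = 13L)
  rec <- preprocess_assays(d$assays)
  setup <- select_species_curve_setup_r3(rec, test_fraction = 0.25,
                                         min_test_chemicals = 6L,
                                         aux_min_train = 10L,
                                         aux_cap = 10L, seed = 3)
  expect_gt(length(setup$study_species), 0L)
  expect_gt(length(setup$aux_species), 0L)
  # recount oracle against the returned split
  test <- rec[rec$chemical_id %in% setup$split$test_chemicals, ]
  train <- rec[rec$chemical_id %in% setup$split$train_chemicals, ]
  tc <- tapply(test$chemical_id, test$species_id,
               function(x) length(unique(x)))
  study_oracle <- intersect(names(tc)[tc >= 6L],
                            unique(train$species_id))
  expect_setequal(setup$study_species, study_oracle)
  trc <- table(train$species_id)
  expect_setequal(setup$aux_species,
                  setdiff(names(trc)[trc >= 10L], study_oracle))
  expect_length(intersect(setup$study_species, setup$aux_species), 0L)

  # every auxiliary species contributes exactly aux_cap rows after capping
  draw <- aquamtl:::.aux_draw(setup, 1L, seed = 3)
  expect_true(all(table(draw$capped$species_id) == 10L))
  expect_setequal(draw$perm, setup$aux_species)
})

test_that("build_species_curve excludes single-task learners and is prefixed", {
  d <- tiny_dataset(n_species = 10L, n_chemicals = 60L, n_assays = 500L,
                    zipf_exponent = 1.2, replicate_rate = 0,
                    bound_rate = 0, seed = 19L)
  rec <- preprocess_assays(d$assays)
  setup <- select_species_curve_setup_r3(rec, 0.25, 6L, 10L,
                                         aux_cap = 10L, seed = 3)
  expect_warning(
    curve <- build_species_curve(
      setup, d$chemicals, d$taxonomy, counts = c(0L, 1L),
      specs = list(learner_spec("st_mean"), learner_spec("mt_mean")),
      n_seeds = 2L, seed = 6),
    "excluded")
  expect_setequal(unique(curve$learner), "mt_mean")
  expect_setequal(unique(curve$anchor), c(0L, 1L))
  expect_error(build_species_curve(
    setup, d$chemicals, d$taxonomy, counts = 99L,
    specs = list(learner_spec("mt_mean"))), "counts must lie")

  # n = 0 baseline exists for every study species group
  base <- curve[curve$anchor == 0L & curve$aggregation == "species", ]
  expect_setequal(unique(base$group), setup$study_species)
})

test_that("bootstrap bands behave like percentile bootstrap", {
  expect_warning(b1 <- bootstrap_bands(0.7), "degenerate")
  expect_equal(unname(b1), c(0.7, 0.7))
  bc <- bootstrap_bands(rep(2, 10))
  expect_equal(unname(bc), c(2, 2))  # constant errors: zero width

  withr::with_seed(8, errs <- runif(30))
  b <- bootstrap_bands(errs, B = 1000, seed = 1)
  expect_lte(b["lower"], mean(errs))
  expect_gte(b["upper"], mean(errs))
  # convergence: B = 10000 agrees with B = 1000 within Monte-Carlo error
  b2 <- bootstrap_bands(errs, B = 10000, seed = 2)
  expect_lt(max(abs(b - b2)), 0.03)
})

test_that("run_experiment orchestrates, audits and reproduces", {
  cfg <- list(
    synth = tiny_cfg(n_species = 5L, n_chemicals = 50L, n_assays = 400L,
                     seed = 23L),
    protocol = "average", seed = 3L,
    learners = c("st_mean", "mt_mean"),
    test_fraction = 0.2, k = 3L, repetitions = 2L,
    out_dir = withr::local_tempdir())
  run <- run_experiment(cfg)
  expect_s3_class(run, "aquamtl_run")
  expect_equal(run$manifest$leakage_audit, "passed")
  expect_true(all(c("synth", "experiment") %in% names(run$manifest$seeds)))
  expect_true(file.exists(file.path(cfg$out_dir, "manifest.json")))
  expect_true(file.exists(file.path(cfg$out_dir, "external.csv")))
  # 3 folds x 2 repetitions = 6 internal estimates per learner
  expect_equal(sum(run$results$internal$learner == "st_mean"), 6L)

  # rerun with the same config: byte-identical deterministic results
  cfg2 <- cfg
  cfg2$out_dir <- NULL
  run2 <- run_experiment(cfg2)
  expect_identical(run$results$external, run2$results$external)
  expect_identical(run$results$internal, run2$results$internal)
})

test_that("the CLI generates datasets from a JSON config", {
  dir <- withr::local_tempdir()
  cfg_file <- file.path(dir, "cfg.json")
  jsonlite::write_json(
    list(synth = list(n_phyla = 2, n_classes_per_phylum = 1,
                      n_species = 4, n_chemicals = 20, n_assays = 60,
                      n_fp_bits = 8, n_physchem = 2, seed = 1)),
    cfg_file, auto_unbox = TRUE)
  out <- file.path(dir, "data")
  expect_message(aquamtl_cli(c("generate", "--config", cfg_file,
                               "--out", out)), "written")
  expect_true(file.exists(file.path(out, "assays.csv")))
  expect_error(aquamtl_cli(character(0)), "usage")
})
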