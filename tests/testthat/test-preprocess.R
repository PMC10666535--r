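test_that("standardize_units converts and drops as declared", {
  rec <- make_records("sp1", c("a", "b", "c"), 2,
                      c(1, 5, 7), units = c("g/L", "mg/L", "ppm-soil"))
  expect_warning(out <- standardize_units(rec), "dropped 1")
  expect_equal(nrow(out), 2L)
  expect_equal(out$endpoint_value, c(1000, 5))  # 1 g/L -> 1000 mg/L
  expect_true(all(out$endpoint_units == "mg/L"))
  expect_equal(attr(out, "dropped_units"), 1L)

  # all-convertible input conserves the row count
  ok <- make_records("sp1", c("a", "b"), 2, c(1, 2),
                     units = c("ug/L", "ppb"))
  out2 <- standardize_units(ok)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$endpoint_value, c(1e-3, 2e-3))
})

test_that("drop_bounded keeps exact rows only", {
  rec <- make_records("sp1", c("a", "b", "c"), 2, c(1, 2, 3),
                      bound = c("exact", "less_than", "greater_than"))
  expect_equal(nrow(drop_bounded(rec)), 1L)
  expect_identical(drop_bounded(rec)$chemical_id, "a")
  expect_identical(drop_bounded(rec[1, ]), rec[1, ])  # all-exact: identity
  expect_warning(empty <- drop_bounded(rec[-1, ]), "all records")
  expect_equal(nrow(empty), 0L)
})

test_that("merge_subspecies averages on the log scale and is idempotent", {
  rec <- make_records("sp1", "a", 2, c(10, 1000),
                      subspecies = c("sub1", "sub2"))
  out <- merge_subspecies(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$endpoint_value, 100)  # 10^((1+3)/2)
  expect_false("subspecies_id" %in% names(out))
  expect_equal(merge_subspecies(out), out)

  # single subspecies: values unchanged
  one <- make_records("sp1", c("a", "b"), 2, c(3, 4), subspecies = "sub1")
  expect_equal(merge_subspecies(one)$endpoint_value, c(3, 4))
})

test_that("aggregate_replicates is the geometric mean over the cell", {
  rec <- make_records("sp1", c("a", "a", "a", "b"), 2, c(2, 4, 8, 5))
  out <- aggregate_replicates(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$endpoint_value[out$chemical_id == "a"], 4)  # (2*4*8)^(1/3)
  expect_equal(out$endpoint_value[out$chemical_id == "b"], 5)  # singleton
  expect_equal(
    aggregate_replicates(make_records("s", c("a", "a"), 1,
                                      c(10, 1000)))$endpoint_value, 100)

  # commutes with row permutation (up to ordering)
  perm <- rec[c(4, 2, 1, 3), ]
  out2 <- aggregate_replicates(perm)
  expect_equal(out2[order(out2$chemical_id), "endpoint_value"],
               out[order(out$chemical_id), "endpoint_value"])

  expect_error(aggregate_replicates(
    make_records("s", "a", 1, -1)), "nonpositive")
  expect_error(aggregate_replicates(
    make_records("s", "a", 1, 1, bound = "less_than")), "bounded")
})

test_that("normalize_duration converts to days and drops missing", {
  rec <- make_records("sp1", c("a", "b", "c", "d"), c(96, NA, 2, -1),
                      value = 1)
  rec$duration_units <- c("hours", "days", "days", "days")
  expect_warning(out <- normalize_duration(rec), "dropped 2")
  expect_equal(out$duration, c(4, 2))  # 96 h -> 4 d; 2 d identity
})

test_that("pipeline order is fixed and row counts never increase", {
  d <- tiny_dataset(replicate_rate = 0.3, bound_rate = 0.15)
  clean <- preprocess_assays(d$assays)
  log <- attr(clean, "pipeline_log")
  expect_true(all(diff(log) <= 0))
  key <- paste(clean$species_id, clean$chemical_id, clean$duration)
  expect_false(anyDuplicated(key) > 0)

  # on replicate-free input, merge and aggregation commute
  rec <- make_records(c("s1", "s1", "s2"), c("a", "b", "a"), 2,
                      c(1, 2, 3))
  ab <- aggregate_replicates(merge_subspecies(rec))
  ba <- merge_subspecies(aggregate_replicates(rec))
  expect_equal(ab, ba)
})

test_that("build_model_table produces the declared design", {
  w <- linear_world(n_species = 3L, n_chem = 20L)
  tab <- build_model_table(w$records, w$chemicals, w$taxonomy,
                           "single_task")
  # target is log10 of the raw endpoint
  expect_equal(sort(tab$y), sort(log10(w$records$endpoint_value)),
               tolerance = 1e-12)
  expect_false(any(grepl("^species_|^class_|^phylum_", colnames(tab$x))))
  # duration is constant in this world, so its log10 column is dropped
  expect_false("log10_duration" %in% colnames(tab$x))

  mt <- build_model_table(w$records, w$chemicals, w$taxonomy, "multi_task")
  expect_true(any(grepl("^species_", colnames(mt$x))))
  # class/phylum one-hots are constant here (one class), hence dropped
  expect_false(any(grepl("^class_|^phylum_", colnames(mt$x))))

  # raw endpoint 100 -> target 2
  rec1 <- make_records("sp01", "chem001", 2, 100)
  t1 <- build_model_table(rec1, w$chemicals, w$taxonomy, "single_task",
                          schema = tab$schema)
  expect_equal(t1$y, 2)

  expect_error(build_model_table(w$records[0, ], w$chemicals, w$taxonomy,
                                 "single_task"), "empty")
})

test_that("schema is fitted on training rows only and re-applied", {
  chems <- make_chemicals(30, missing_rate = 0.3, seed = 9L)
  species <- c("s1", "s2")
  rec <- make_records(rep(species, each = 20),
                      rep(chems$chemical_id[1:20], 2),
                      duration = rep(c(1, 4), 20), value = runif(40, 1, 50))
  tax <- make_taxonomy(species, class_name = c("c1", "c2"))
  train <- rec[rec$chemical_id %in% chems$chemical_id[1:15], ]
  test <- rec[!rec$chemical_id %in% chems$chemical_id[1:15], ]
  tr <- build_model_table(train, chems, tax, "multi_task")
  te <- build_model_table(test, chems, tax, "multi_task",
                          schema = tr$schema)
  expect_identical(colnames(te$x), colnames(tr$x))
  # imputation medians come from training chemicals only
  if ("pc_2_missing" %in% colnames(tr$x)) {
    med <- median(chems$pc_2[match(unique(train$chemical_id),
                                   chems$chemical_id)], na.rm = TRUE)
    miss_rows <- te$x[, "pc_2_missing"] == 1
    if (any(miss_rows))
      expect_true(all(abs(te$x[miss_rows, "pc_2"] - med) < 1e-12))
  }
  # wrong mode is refused
  expect_error(build_model_table(test, chems, tax, "single_task",
                                 schema = tr$schema), "mode")
})
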