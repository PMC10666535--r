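#' Default concentration unit conversion table
#'
#' Multiplicative factors to the canonical mass-concentration unit, mg/L.
#' `ppm`/`ppb` are treated as mg/L and ug/L respectively (dilute aqueous
#' solutions).  Units absent from the table (e.g. molar units, which would
#' need a molecular weight) are unconvertible and their rows are dropped.
#'
#' @return data.frame with columns `unit`, `factor_to_mg_l`.
#' @export
default_unit_table <- function() {
  data.frame(
    unit = c("mg/L", "g/L", "ug/L", "µg/L", "ng/L", "ppm", "ppb"),
    factor_to_mg_l = c(1, 1000, 1e-3, 1e-3, 1e-6, 1, 1e-3),
    stringsAsFactors = FALSE)
}

.drop_count <- function(records, n, reason) {
  if (n > 0)
    warning(sprintf("dropped %d row(s): %s", n, reason), call. = FALSE)
  records
}

#' Standardize endpoint concentration units
#'
#' Converts all endpoint values to a single canonical unit; rows whose unit
#' is not in the conversion table are dropped with a warning (never a
#' crash), and the number of dropped rows is recorded in the
#' `"dropped_units"` attribute.
#'
#' @param records AssayRecord data.frame (needs `endpoint_value`,
#'   `endpoint_units`).
#' @param unit_table conversion table, see [default_unit_table()].
#' @param canonical canonical unit label after conversion.
#' @return records with harmonized `endpoint_value`/`endpoint_units`.
#' @export
standardize_units <- function(records, unit_table = default_unit_table(),
                              canonical = "mg/L") {
  .stopifnot_cols(records, c("endpoint_value", "endpoint_units"))
  fac <- setNames(unit_table$factor_to_mg_l, unit_table$unit)
  known <- records$endpoint_units %in% names(fac)
  out <- records[known, , drop = FALSE]
  out$endpoint_value <- out$endpoint_value * unname(fac[out$endpoint_units])
  out$endpoint_units <- canonical
  out <- .drop_count(out, sum(!known), "unconvertible endpoint unit")
  attr(out, "dropped_units") <- sum(!known)
  out
}

#' Drop bounded endpoint records
#'
#' Endpoints flagged as bounds (less-than, greater-than, between) reflect
#' detection limits rather than measured LC50 values and are disregarded;
#' only `bound == "exact"` rows survive.
#'
#' @param records AssayRecord data.frame with a `bound` column.
#' @return the exact-bound subset (warns if it is empty).
#' @export
drop_bounded <- function(records) {
  .stopifnot_cols(records, "bound")
  out <- records[records$bound == "exact", , drop = FALSE]
  if (nrow(out) == 0L && nrow(records) > 0L)
    warning("all records were bounded; empty table returned", call. = FALSE)
  out
}

#' Merge subspecies into their parent species
#'
#' Toxicity is modelled on the species level, so rows recorded for
#' subspecies are folded into the parent species.  Rows that become
#' duplicates of the same (species, chemical, duration) cell are averaged
#' on the log10 scale (equivalently, geometric mean of raw values),
#' consistent with replicate aggregation.  Idempotent.
#'
#' @param records AssayRecord data.frame; `subspecies_id` may be `NA`.
#' @return records without a `subspecies_id` column, one row per
#'   (species, chemical, duration, bound) cell among merged rows.
#' @export
merge_subspecies <- function(records) {
  if (!"subspecies_id" %in% names(records)) return(records)
  has_sub <- any(!is.na(records$subspecies_id))
  records$subspecies_id <- NULL
  if (!has_sub) return(records)  # nothing recorded below species level
  key <- paste(.assay_key(records), records$bound, sep = "\r")
  if (!anyDuplicated(key)) return(records)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  gm <- tapply(records$endpoint_value, key, geometric_mean)
  out$endpoint_value <- unname(gm[key[first]])
  rownames(out) <- NULL
  out
}

#' Aggregate replicate measurements by geometric mean
#'
#' Experiments repeated under identical conditions (same species, chemical
#' and duration) are collapsed to one row whose endpoint is the geometric
#' mean of the raw values, so that no cell is over-represented in model
#' training.  Requires bounded rows to have been removed already.
#'
#' @param records exact-bound AssayRecord data.frame.
#' @return records with a unique (species, chemical, duration) key.
#' @export
aggregate_replicates <- function(records) {
  .stopifnot_cols(records, c("species_id", "chemical_id", "duration",
                             "endpoint_value"))
  if (any(records$bound != "exact"))
    stop("aggregate_replicates expects bounded rows to be removed first")
  if (any(records$endpoint_value <= 0))
    stop("nonpositive endpoint value reached aggregation (upstream bug)")
  key <- .assay_key(records)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  gm <- tapply(records$endpoint_value, key, geometric_mean)
  out$endpoint_value <- unname(gm[key[first]])
  rownames(out) <- NULL
  out
}

#' Normalize exposure durations to days
#'
#' @param records AssayRecord data.frame with `duration` and optionally
#'   `duration_units` (`"days"` assumed when absent; `"hours"` divided by
#'   24).  Rows with missing or nonpositive duration are dropped with a
#'   warning.
#' @return records with `duration` in days.
#' @export
normalize_duration <- function(records) {
  .stopifnot_cols(records, "duration")
  dur <- records$duration
  if ("duration_units" %in% names(records)) {
    u <- records$duration_units
    hours <- !is.na(u) & u %in% c("h", "hr", "hours")
    dur[hours] <- dur[hours] / 24
    known <- is.na(u) | u %in% c("h", "hr", "hours", "d", "day", "days")
    dur[!known] <- NA_real_
    records$duration_units <- NULL
  }
  keep <- !is.na(dur) & dur > 0
  records$duration <- dur
  out <- records[keep, , drop = FALSE]
  .drop_count(out, sum(!keep), "missing or nonpositive duration")
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: unit standardization -> bound filtering -> subspecies
#' merge -> replicate aggregation (geometric mean) -> duration
#' normalization.  Row counts never increase at any stage.
#'
#' @param records raw AssayRecord data.frame.
#' @param unit_table,canonical see [standardize_units()].
#' @return cleaned records ready for [build_model_table()]; the
#'   `"pipeline_log"` attribute records per-stage row counts.
#' @export
preprocess_assays <- function(records, unit_table = default_unit_table(),
                              canonical = "mg/L") {
  log <- c(input = nrow(records))
  records <- standardize_units(records, unit_table, canonical)
  log["units"] <- nrow(records)
  records <- drop_bounded(records)
  log["bounds"] <- nrow(records)
  records <- merge_subspecies(records)
  log["subspecies"] <- nrow(records)
  records <- aggregate_replicates(records)
  log["replicates"] <- nrow(records)
  records <- normalize_duration(records)
  log["duration"] <- nrow(records)
  attr(records, "pipeline_log") <- log
  records
}

.one_hot <- function(values, levels, prefix) {
  m <- matrix(0, nrow = length(values), ncol = length(levels),
              dimnames = list(NULL, paste0(prefix, levels)))
  hit <- match(values, levels)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

#' Assemble a modelling table from cleaned assay records
#'
#' Joins chemical features onto assay rows and produces the numeric design
#' matrix the learners consume.  The target is `log10(endpoint_value)` and
#' duration enters as `log10(days)`.  Physchem columns with any training
#' missingness gain a paired `*_missing` indicator and are imputed to the
#' training-column median; columns constant across training rows are
#' removed.  In `multi_task` mode one-hot encodings of species, class and
#' phylum are appended; `single_task` tables carry no taxonomy columns.
#'
#' When `schema` is supplied (from a previously built training table) all
#' feature-selection and imputation decisions are *re-applied*, never
#' re-fitted — this is what keeps test chemicals out of every fitted
#' statistic.  Rows are canonicalized (sorted by chemical, species,
#' duration) so fits are invariant to input row order.
#'
#' @param records cleaned records from [preprocess_assays()] (or
#'   equivalent: aggregated, unit-normalized, exact bounds only).
#' @param chemicals chemical feature table (`chemical_id` + `fp_*`/`pc_*`).
#' @param taxonomy species taxonomy table.
#' @param mode `"single_task"` or `"multi_task"`.
#' @param schema optional training schema to re-apply.
#' @return an object of class `model_table`: list with design matrix `x`,
#'   target `y`, id vectors `species`, `class_name`, `phylum_name`,
#'   `chemical`, `duration`, the `mode` and the fitted `schema`.
#' @export
build_model_table <- function(records, chemicals, taxonomy,
                              mode = c("single_task", "multi_task"),
                              schema = NULL) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("empty records")
  .stopifnot_cols(records, c("species_id", "chemical_id", "duration",
                             "endpoint_value"))
  .stopifnot_cols(chemicals, "chemical_id", "chemicals")
  if (any(records$endpoint_value <= 0))
    stop("nonpositive endpoint values: log10 target undefined")

  records <- records[.canonical_order(records), , drop = FALSE]
  ci <- match(records$chemical_id, chemicals$chemical_id)
  if (anyNA(ci)) stop("records reference unknown chemicals")
  ti <- match(records$species_id, taxonomy$species_id)
  if (anyNA(ti)) stop("records reference species missing from taxonomy")

  feat_cols <- setdiff(names(chemicals), "chemical_id")
  chem_x <- as.matrix(chemicals[ci, feat_cols, drop = FALSE])
  x <- cbind(chem_x, log10_duration = log10(records$duration))

  if (is.null(schema)) {
    miss_cols <- feat_cols[vapply(feat_cols, function(cn)
      anyNA(chem_x[, cn]), logical(1))]
    medians <- vapply(miss_cols, function(cn)
      median(chem_x[, cn], na.rm = TRUE), numeric(1))
    medians[!is.finite(medians)] <- 0  # all-missing training column
    schema <- list(mode = mode, miss_cols = miss_cols, medians = medians,
                   species_levels = sort(unique(records$species_id)),
                   class_levels = sort(unique(taxonomy$class_name[ti])),
                   phylum_levels = sort(unique(taxonomy$phylum_name[ti])))
    fitted <- TRUE
  } else {
    if (!identical(schema$mode, mode))
      stop("schema was fitted in mode '", schema$mode, "'")
    fitted <- FALSE
  }

  if (length(schema$miss_cols)) {
    ind <- matrix(0, nrow(x), length(schema$miss_cols),
                  dimnames = list(NULL, paste0(schema$miss_cols,
                                               "_missing")))
    for (k in seq_along(schema$miss_cols)) {
      cn <- schema$miss_cols[k]
      na <- is.na(x[, cn])
      ind[na, k] <- 1
      x[na, cn] <- schema$medians[[cn]]
    }
    x <- cbind(x, ind)
  }
  # columns that were not imputed but contain NA (missingness first seen at
  # prediction time): impute to training median of that column
  if (anyNA(x)) {
    for (cn in colnames(x)[colSums(is.na(x)) > 0])
      x[is.na(x[, cn]), cn] <- median(x[, cn], na.rm = TRUE)
  }

  if (mode == "multi_task") {
    x <- cbind(x,
               .one_hot(records$species_id, schema$species_levels,
                        "species_"),
               .one_hot(taxonomy$class_name[ti], schema$class_levels,
                        "class_"),
               .one_hot(taxonomy$phylum_name[ti], schema$phylum_levels,
                        "phylum_"))
  }

  if (fitted) {
    keep <- apply(x, 2, function(col) length(unique(col)) > 1L)
    schema$feature_names <- colnames(x)[keep]
  }
  x <- x[, schema$feature_names, drop = FALSE]
  rownames(x) <- NULL

  structure(list(x = x, y = log10(records$endpoint_value),
                 species = records$species_id,
                 class_name = taxonomy$class_name[ti],
                 phylum_name = taxonomy$phylum_name[ti],
                 chemical = records$chemical_id,
                 duration = records$duration,
                 mode = mode, schema = schema),
            class = "model_table")
}

#' @export
print.model_table <- function(x, ...) {
  cat(sprintf("<model_table> %d rows, %d features, mode=%s, %d species\n",
              nrow(x$x), ncol(x$x), x$mode, length(unique(x$species))))
  invisible(x)
}

# subset a model table by row index, keeping the schema
.table_subset <- function(table, idx) {
  out <- table
  out$x <- table$x[idx, , drop = FALSE]
  out$y <- table$y[idx]
  for (f in c("species", "class_name", "phylum_name", "chemical",
              "duration"))
    out[[f]] <- table[[f]][idx]
  out
}
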