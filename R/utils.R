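`%||%` <- function(x, y) if (is.null(x)) y else x

#' Geometric mean
#'
#' Geometric mean of strictly positive values, computed on the log scale for
#' numerical stability.  This is the aggregation the REACH guidance
#' prescribes for replicate toxicity measurements.
#'
#' @param x numeric vector of positive values.
#' @return a single number, `exp(mean(log(x)))`.
#' @export
#' @examples
#' geometric_mean(c(10, 1000)) # 100
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("geometric_mean of empty vector")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("geometric_mean requires finite positive values")
  exp(mean(log(x)))
}

# shared assay-record key
.assay_key <- function(records) {
  paste(records$species_id, records$chemical_id,
        format(records$duration, digits = 12), sep = "\r")
}

# canonical row order used everywhere a table is materialized, so that fits
# are invariant to the ordering of the incoming records
.canonical_order <- function(records) {
  order(records$chemical_id, records$species_id, records$duration)
}

.stopifnot_cols <- function(df, cols, what = "records") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s lacks required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

# deterministic small sub-seed derived from a base seed; stays < 2^31
.subseed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(k) %% 1009L
}
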