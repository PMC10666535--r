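#' Configuration for the synthetic ecotoxicology data generator
#'
#' The generator emulates the structure of large aquatic-toxicity
#' collections: a nested phylum -> class -> species taxonomy, a long-tailed
#' (Zipf) distribution of assay counts over species, sparse
#' species-by-chemical coverage, binary fingerprint plus continuous
#' physico-chemical chemical descriptors, duration-dependent log10(LC50)
#' targets driven by a hydrophobicity-like descriptor, replicate
#' measurements with multiplicative lognormal noise, and bounded ("<"/">")
#' detection-limit records.
#'
#' Defaults mirror the full-scale collection the package is designed
#' around: 24816 assays over 351 species (9 phyla, ~20 classes) and 2674
#' chemicals with 1024 fingerprint bits.  The toxicity surface is a
#' narcosis-style baseline: per-species intercepts alpha_s (a sum of
#' phylum-, class- and species-level Gaussian draws, so taxonomy carries
#' real signal) plus a per-species slope w_s on the log Kow column, with
#' slope mean -0.85 (the classic baseline-narcosis coefficient), a global
#' duration effect of -0.3 per log10(day) (toxicity grows with exposure)
#' and residual scale 0.5 log10 units (typical inter-test variability).
#'
#' @param n_phyla,n_classes_per_phylum,n_species taxonomy dimensions.
#' @param n_chemicals,n_assays table sizes.
#' @param n_fp_bits fingerprint width (1024 matches ECFP4 hashing).
#' @param n_physchem number of continuous descriptors; the first one,
#'   `pc_logkow`, plays the hydrophobicity role in the ground truth.
#' @param missing_rate fraction of physchem entries masked missing.
#' @param zipf_exponent exponent of the truncated Zipf law for per-species
#'   assay counts (larger = heavier concentration on few species).
#' @param sigma_phylum,sigma_class,sigma_species scales of the nested
#'   Gaussian intercept components.
#' @param slope_mean,slope_sd distribution of per-species hydrophobicity
#'   slopes.
#' @param intercept_mean global mean of log10(LC50) in mg/L.
#' @param duration_effect coefficient on log10(duration in days).
#' @param sigma_noise residual standard deviation (log10 units).
#' @param replicate_rate fraction of assay cells receiving 2-4 replicate
#'   rows; `replicate_sd` is their multiplicative noise in log10 units.
#' @param bound_rate fraction of rows flagged as "<" or ">" bounds.
#' @param durations discrete set of exposure durations (days) sampled
#'   uniformly; the standard acute/chronic test lengths by default.
#' @param seed integer seed; all generator functions are deterministic
#'   given the config.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_phyla = 9L, n_classes_per_phylum = 2L,
                         n_species = 351L, n_chemicals = 2674L,
                         n_assays = 24816L, n_fp_bits = 1024L,
                         n_physchem = 10L, missing_rate = 0.1,
                         zipf_exponent = 1.2,
                         sigma_phylum = 0.5, sigma_class = 0.3,
                         sigma_species = 0.3,
                         slope_mean = -0.85, slope_sd = 0.15,
                         intercept_mean = 1.5,
                         duration_effect = -0.3, sigma_noise = 0.5,
                         replicate_rate = 0.1, replicate_sd = 0.1,
                         bound_rate = 0.05,
                         durations = c(1, 2, 4, 21), seed = 1L) {
  cfg <- list(n_phyla = as.integer(n_phyla),
              n_classes_per_phylum = as.integer(n_classes_per_phylum),
              n_species = as.integer(n_species),
              n_chemicals = as.integer(n_chemicals),
              n_assays = as.integer(n_assays),
              n_fp_bits = as.integer(n_fp_bits),
              n_physchem = as.integer(n_physchem),
              missing_rate = missing_rate,
              zipf_exponent = zipf_exponent,
              sigma_phylum = sigma_phylum, sigma_class = sigma_class,
              sigma_species = sigma_species,
              slope_mean = slope_mean, slope_sd = slope_sd,
              intercept_mean = intercept_mean,
              duration_effect = duration_effect,
              sigma_noise = sigma_noise,
              replicate_rate = replicate_rate, replicate_sd = replicate_sd,
              bound_rate = bound_rate,
              durations = durations, seed = as.integer(seed))
  with(cfg, {
    if (n_phyla < 1L || n_classes_per_phylum < 1L || n_species < 1L)
      stop("taxonomy counts must be positive")
    if (n_chemicals < 1L) stop("n_chemicals must be positive")
    if (n_fp_bits < 1L) stop("n_fp_bits must be >= 1")
    if (n_assays < n_species)
      stop("n_assays must be >= n_species (every species gets >= 1 assay)")
    if (any(c(sigma_phylum, sigma_class, sigma_species, sigma_noise,
              slope_sd, replicate_sd) < 0))
      stop("all sigma parameters must be nonnegative")
    if (zipf_exponent <= 0) stop("zipf_exponent must be positive")
    for (p in c(missing_rate, replicate_rate, bound_rate))
      if (p < 0 || p > 1) stop("rates must lie in [0, 1]")
    if (any(durations <= 0)) stop("durations must be positive (days)")
  })
  structure(cfg, class = "synth_config")
}

.id_pad <- function(prefix, i, n) sprintf("%s%0*d", prefix, nchar(n), i)

#' Generate a nested species taxonomy
#'
#' Assigns `n_species` species to classes nested within phyla.  Every class
#' is guaranteed nonempty whenever there are at least as many species as
#' classes; remaining species are assigned uniformly at random.
#'
#' @param cfg a [synth_config()].
#' @return a data.frame with columns `species_id`, `class_name`,
#'   `phylum_name`, one row per species.
#' @export
generate_taxonomy <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_classes <- cfg$n_phyla * cfg$n_classes_per_phylum
  classes <- data.frame(
    class_name = .id_pad("cls", seq_len(n_classes), n_classes),
    phylum_name = rep(.id_pad("phy", seq_len(cfg$n_phyla), cfg$n_phyla),
                      each = cfg$n_classes_per_phylum),
    stringsAsFactors = FALSE)
  withr::with_seed(.subseed(cfg$seed, 1L), {
    cls_of <- if (cfg$n_species >= n_classes) {
      c(seq_len(n_classes),
        sample.int(n_classes, cfg$n_species - n_classes, replace = TRUE))
    } else {
      sample.int(n_classes, cfg$n_species)
    }
  })
  data.frame(species_id = .id_pad("sp", seq_len(cfg$n_species),
                                  cfg$n_species),
             class_name = classes$class_name[cls_of],
             phylum_name = classes$phylum_name[cls_of],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic chemical feature table
#'
#' Each chemical carries `n_fp_bits` binary fingerprint columns (`fp_*`,
#' sparse: per-bit activation probabilities drawn from Beta(1, 10)) and
#' `n_physchem` continuous descriptors (`pc_*`).  The first descriptor,
#' `pc_logkow`, is drawn N(2, 1.5^2) — a realistic log Kow range — and
#' drives toxicity in the ground truth.  A `missing_rate` fraction of
#' physchem entries is set `NA`; downstream feature assembly pairs such
#' columns with missingness indicators.
#'
#' @inheritParams generate_taxonomy
#' @return a data.frame with `chemical_id`, fingerprint and physchem
#'   columns.
#' @export
generate_chemicals <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_chemicals
  withr::with_seed(.subseed(cfg$seed, 2L), {
    p_bit <- stats::rbeta(cfg$n_fp_bits, 1, 10)
    fp <- matrix(rbinom(n * cfg$n_fp_bits, 1L,
                        rep(p_bit, each = n)), nrow = n)
    colnames(fp) <- .id_pad("fp_", seq_len(cfg$n_fp_bits), cfg$n_fp_bits)
    pc <- matrix(rnorm(n * cfg$n_physchem), nrow = n)
    pc[, 1] <- 2 + 1.5 * pc[, 1]
    colnames(pc) <- c("pc_logkow",
                      if (cfg$n_physchem > 1L)
                        .id_pad("pc_", seq_len(cfg$n_physchem)[-1],
                                cfg$n_physchem))
    if (cfg$missing_rate > 0) {
      mask <- matrix(runif(length(pc)) < cfg$missing_rate, nrow = n)
      pc[mask] <- NA_real_
    }
    data.frame(chemical_id = .id_pad("chem", seq_len(n), n), fp, pc,
               stringsAsFactors = FALSE)
  })
}

# truncated Zipf counts summing exactly to total, every rank >= 1
.zipf_counts <- function(n_ranks, exponent, total) {
  w <- seq_len(n_ranks)^(-exponent)
  w <- w / sum(w)
  extra <- total - n_ranks
  base <- floor(w * extra)
  rem <- extra - sum(base)
  if (rem > 0) {
    frac <- w * extra - base
    base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  as.integer(base + 1L)
}

#' Generate synthetic assay records with known ground truth
#'
#' Draws per-species assay counts from a truncated Zipf law (rank 1 =
#' first species), samples chemicals and durations for each assay, and
#' computes the target
#' `log10(LC50) = alpha_s + w_s * logKow + duration_effect * log10(days) + eps`.
#' Raw endpoint values are `10^target` in mg/L.  A `replicate_rate`
#' fraction of cells is expanded into 2-4 replicate rows with
#' multiplicative lognormal noise on the raw scale (so the geometric mean
#' is the natural aggregator), and a `bound_rate` fraction of rows is
#' flagged `"<"`/`">"` with the value clamped to the species' 5th/95th raw
#' percentile, mimicking detection limits.
#'
#' Chemicals with a missing `pc_logkow` entry still have a true
#' hydrophobicity (the truth is computed before masking is applied to an
#' independent draw), so missingness does not distort the surface.
#'
#' @inheritParams generate_taxonomy
#' @param taxonomy output of [generate_taxonomy()].
#' @param chemicals output of [generate_chemicals()].
#' @return a list with `assays` (an AssayRecord data.frame: `species_id`,
#'   `subspecies_id`, `class_name`, `phylum_name`, `chemical_id`,
#'   `duration`, `endpoint_value`, `endpoint_units`, `bound`) and `truth`
#'   (per-species effect table plus global coefficients).
#' @export
generate_assays <- function(cfg, taxonomy, chemicals) {
  stopifnot(inherits(cfg, "synth_config"))
  if (nrow(taxonomy) == 0L || nrow(chemicals) == 0L)
    stop("taxonomy and chemicals must be nonempty")
  .stopifnot_cols(taxonomy, c("species_id", "class_name", "phylum_name"),
                  "taxonomy")

  withr::with_seed(.subseed(cfg$seed, 3L), {
    phyla <- sort(unique(taxonomy$phylum_name))
    classes <- sort(unique(taxonomy$class_name))
    eff_phylum <- setNames(rnorm(length(phyla), 0, cfg$sigma_phylum), phyla)
    eff_class <- setNames(rnorm(length(classes), 0, cfg$sigma_class),
                          classes)
    eff_species <- rnorm(nrow(taxonomy), 0, cfg$sigma_species)
    slope <- rnorm(nrow(taxonomy), cfg$slope_mean, cfg$slope_sd)

    truth <- data.frame(
      species_id = taxonomy$species_id,
      phylum_component = unname(eff_phylum[taxonomy$phylum_name]),
      class_component = unname(eff_class[taxonomy$class_name]),
      species_component = eff_species,
      slope = slope,
      stringsAsFactors = FALSE)
    truth$alpha <- cfg$intercept_mean + truth$phylum_component +
      truth$class_component + truth$species_component

    counts <- .zipf_counts(nrow(taxonomy), cfg$zipf_exponent, cfg$n_assays)
    sp_idx <- rep(seq_len(nrow(taxonomy)), counts)
    n <- length(sp_idx)
    chem_idx <- sample.int(nrow(chemicals), n, replace = TRUE)
    dur <- cfg$durations[sample.int(length(cfg$durations), n,
                                    replace = TRUE)]

    # true hydrophobicity: observed value where present, fresh draw where
    # masked (the chemical still *has* a log Kow, we just did not observe it)
    kow <- chemicals$pc_logkow
    kow[is.na(kow)] <- rnorm(sum(is.na(kow)), 2, 1.5)

    target <- truth$alpha[sp_idx] + truth$slope[sp_idx] * kow[chem_idx] +
      cfg$duration_effect * log10(dur) + rnorm(n, 0, cfg$sigma_noise)

    assays <- data.frame(
      species_id = taxonomy$species_id[sp_idx],
      subspecies_id = NA_character_,
      class_name = taxonomy$class_name[sp_idx],
      phylum_name = taxonomy$phylum_name[sp_idx],
      chemical_id = chemicals$chemical_id[chem_idx],
      duration = dur,
      endpoint_value = 10^target,
      endpoint_units = "mg/L",
      bound = "exact",
      stringsAsFactors = FALSE)

    # replicate expansion on the raw scale
    if (cfg$replicate_rate > 0) {
      is_rep <- runif(n) < cfg$replicate_rate
      if (any(is_rep)) {
        k <- (2:4)[sample.int(3L, sum(is_rep), replace = TRUE)]
        rep_rows <- assays[rep(which(is_rep), k), , drop = FALSE]
        noise <- 10^rnorm(nrow(rep_rows), 0, cfg$replicate_sd)
        rep_rows$endpoint_value <- rep_rows$endpoint_value * noise
        assays <- rbind(assays[!is_rep, , drop = FALSE], rep_rows)
      }
    }

    if (cfg$bound_rate > 0) {
      nb <- nrow(assays)
      is_bnd <- runif(nb) < cfg$bound_rate
      if (any(is_bnd)) {
        lo <- tapply(assays$endpoint_value, assays$species_id, quantile,
                     probs = 0.05, names = FALSE)
        hi <- tapply(assays$endpoint_value, assays$species_id, quantile,
                     probs = 0.95, names = FALSE)
        side <- sample(c("less_than", "greater_than"), sum(is_bnd),
                       replace = TRUE)
        sp <- assays$species_id[is_bnd]
        assays$bound[is_bnd] <- side
        assays$endpoint_value[is_bnd] <-
          ifelse(side == "less_than", lo[sp], hi[sp])
      }
    }
    rownames(assays) <- NULL
    list(assays = assays,
         truth = list(species = truth,
                      intercept_mean = cfg$intercept_mean,
                      duration_effect = cfg$duration_effect,
                      sigma_noise = cfg$sigma_noise))
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_taxonomy()],
#' [generate_chemicals()] and [generate_assays()].
#'
#' @inheritParams generate_taxonomy
#' @return list with `taxonomy`, `chemicals`, `assays`, `truth`.
#' @export
generate_dataset <- function(cfg) {
  taxonomy <- generate_taxonomy(cfg)
  chemicals <- generate_chemicals(cfg)
  ga <- generate_assays(cfg, taxonomy, chemicals)
  list(taxonomy = taxonomy, chemicals = chemicals,
       assays = ga$assays, truth = ga$truth)
}

#' Write a synthetic dataset to delimited text files
#'
#' Writes `assays.csv`, `chemicals.csv` and `taxonomy.csv` (UTF-8, header
#' row, "." decimal separator) plus a `ground_truth.json` sidecar that the
#' modelling pipeline never reads.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(dataset$assays, file.path(dir, "assays.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(dataset$chemicals, file.path(dir, "chemicals.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(dataset$taxonomy, file.path(dir, "taxonomy.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(dataset$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
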