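# Shared fixtures: everything is generated in code at test time.

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_phyla = 2L, n_classes_per_phylum = 2L, n_species = 8L,
         n_chemicals = 40L, n_assays = 320L, n_fp_bits = 16L,
         n_physchem = 3L, seed = 11L),
    list(...))
  do.call(synth_config, args)
}

tiny_dataset <- function(...) generate_dataset(tiny_cfg(...))

# hand-built assay records with full control over every column
make_records <- function(species, chemical, duration, value,
                         units = "mg/L", bound = "exact",
                         subspecies = NA_character_,
                         class_name = "c1", phylum_name = "p1") {
  data.frame(species_id = species, subspecies_id = subspecies,
             class_name = class_name, phylum_name = phylum_name,
             chemical_id = chemical, duration = duration,
             endpoint_value = value, endpoint_units = units,
             bound = bound, stringsAsFactors = FALSE)
}

# minimal chemical table: one informative continuous feature plus a
# handful of fingerprint bits, no missingness unless asked for
make_chemicals <- function(n, seed = 1L, missing_rate = 0) {
  withr::with_seed(seed, {
    df <- data.frame(
      chemical_id = sprintf("chem%03d", seq_len(n)),
      fp_1 = rbinom(n, 1L, 0.4), fp_2 = rbinom(n, 1L, 0.4),
      fp_3 = rbinom(n, 1L, 0.4),
      pc_logkow = rnorm(n, 2, 1.5), pc_2 = rnorm(n),
      stringsAsFactors = FALSE)
    if (missing_rate > 0)
      df$pc_2[runif(n) < missing_rate] <- NA_real_
    df
  })
}

make_taxonomy <- function(species, class_name = "c1", phylum_name = "p1") {
  data.frame(species_id = species, class_name = class_name,
             phylum_name = phylum_name, stringsAsFactors = FALSE)
}

# clean linear world: log10(LC50) = alpha_s + slope * logkow, exact
# (no duration effect, no noise); useful as a learner sanity floor
linear_world <- function(n_species = 4L, n_chem = 60L, slope = -0.8,
                         alphas = NULL, noise = 0, seed = 5L) {
  chems <- make_chemicals(n_chem, seed = seed)
  species <- sprintf("sp%02d", seq_len(n_species))
  alphas <- alphas %||% seq(0.5, by = 0.5, length.out = n_species)
  withr::with_seed(seed + 1L, {
    rows <- expand.grid(species_id = species,
                        chemical_id = chems$chemical_id,
                        stringsAsFactors = FALSE)
    kow <- chems$pc_logkow[match(rows$chemical_id, chems$chemical_id)]
    y <- alphas[match(rows$species_id, species)] + slope * kow +
      rnorm(nrow(rows), 0, noise)
  })
  records <- make_records(rows$species_id, rows$chemical_id,
                          duration = 2, value = 10^y)
  list(records = records, chemicals = chems,
       taxonomy = make_taxonomy(species), alphas = alphas, slope = slope)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
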