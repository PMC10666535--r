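# aquamtl

Meta-learning and multi-task QSAR regression models for aquatic toxicity.

## The problem

Ecotoxicological risk assessment needs the LC50 — the concentration of a
chemical lethal to 50% of test organisms after a given exposure duration —
for many (species, chemical, duration) combinations, but measuring it means
animal testing. QSAR models predict `log10(LC50)` from chemical structure
descriptors instead. Aquatic toxicity collections decompose into one
regression task per species, and most of those tasks are low-resource: the
assay counts per species are heavy-tailed, so a handful of species carry
thousands of assays while most species have only a few. The scientific
question this package operationalizes is *when and how knowledge sharing
across species tasks helps*: it implements single-task baselines, pooled
multi-task models, stacked ensembling, multi-task neural networks,
fine-tuning, model-agnostic meta-learning (MAML) and transformational
machine learning (TML) behind one fit/predict contract, evaluates them with
chemicals-disjoint splits (test compounds are never seen in training, in
any form), and probes the low-resource regime with two learning-curve
designs.

For each assay the models see 1024-bit binary ECFP4-style fingerprint
columns, continuous physico-chemical descriptors (with missingness
indicators), `log10(duration in days)` and — for multi-task families —
one-hot species/class/phylum encodings. The target is `log10(LC50)` in
mg/L. Performance is RMSE in log10 units, aggregated per species or per
chemical with equal group weights, and algorithms are compared with the
Friedman test plus Nemenyi critical differences.

Everything is testable offline: a synthetic-data generator emulates the
sparse species-by-chemical structure (nested taxonomy, truncated-Zipf
assay counts, narcosis-style hydrophobicity-driven toxicity surface with
taxonomy-correlated species effects, replicate measurements, bounded
detection-limit records) with known ground truth.

## Worked example

```r
library(aquamtl)

cfg <- synth_config(n_species = 20, n_phyla = 4, n_classes_per_phylum = 2,
                    n_chemicals = 200, n_assays = 2500, n_fp_bits = 128,
                    n_physchem = 6, seed = 2024)
dataset <- generate_dataset(cfg)
records <- preprocess_assays(dataset$assays)
attr(records, "pipeline_log")
#>      input      units     bounds subspecies replicates   duration
#>       3064       3064       2908       2908       1935       1935

split <- split_by_chemicals(unique(records$chemical_id),
                            test_fraction = 0.2, seed = 1)
specs <- list(learner_spec("st_mean"), learner_spec("st_rf", ntree = 200),
              learner_spec("mt_mean"), learner_spec("mt_rf", ntree = 200))
preds <- evaluate_split(specs, records, split,
                        dataset$chemicals, dataset$taxonomy)
```

Aggregating the held-out-chemical predictions per learner:

```
 learner rmse_by_chemical rmse_by_species
 mt_mean            1.423           1.578
   mt_rf            0.592           0.667
 st_mean            1.121           1.375
   st_rf            0.679           0.884
```

The replicate expansion inflates 2 500 drawn assays to 3 064 rows; unit
standardization keeps all rows (one unit in play), bound filtering removes
the detection-limit records, and geometric-mean replicate aggregation
collapses the table to 1 935 unique (species, chemical, duration) cells.
Both forests beat the mean baselines by a wide margin, and the multi-task
forest — which sees all species plus taxonomy encodings — beats the
single-task forests fit per species. An RMSE of 1.0 on this scale means
predictions within a factor 10 of the true concentration; the forests here
are well inside that band on average. The 5-subfold, 3-repetition internal
validation (15 estimates per learner) feeds the Friedman comparison:

```r
cv <- run_internal_validation(specs, train_records, dataset$chemicals,
                              dataset$taxonomy, k = 5, repetitions = 3,
                              seed = 2)
friedman_nemenyi(sapply(split(cv$rmse, cv$learner), identity))
#> mean ranks: mt_mean 4, mt_rf 1, st_mean 3, st_rf 2
#> chi^2_F = 45, p ~ 0, CD = 1.211
```

so the ranking `mt_rf < st_rf < st_mean < mt_mean` is significant at the
Nemenyi critical difference for adjacent-but-one pairs.

Learning-curve experiments (`select_study_species_r2()` +
`build_assay_curve()` for assays-per-species anchors,
`select_species_curve_setup_r3()` + `build_species_curve()` for
auxiliary-species counts) and the orchestrating `run_experiment()` /
command-line interface (`inst/cli/aquamtl.R`) are documented in the
vignette `vignettes/meta-learning-aquatic-qsar.Rmd`.

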