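Package: aquamtl
Title: Meta-Learning and Multi-Task QSAR Models for Aquatic Toxicity
Version: 0.1.0
Authors@R:
    person("aquamtl", "authors", role = c("aut", "cre"),
           email = "aquamtl@example.org")
Description: Tools for building and comparing single-task, multi-task and
    meta-learning QSAR regression models of aquatic toxicity (log10 LC50)
    across species, chemicals and exposure durations. Provides an
    ECOTOX-style preprocessing pipeline (unit standardization, bound
    filtering, subspecies merging, geometric-mean replicate aggregation),
    ten learner families behind one fit/predict contract (mean baselines,
    random forests, a stacked ensemble, neural networks, fine-tuning,
    model-agnostic meta-learning and transformational machine learning),
    chemicals-disjoint evaluation with Friedman/Nemenyi comparison, two
    learning-curve experiment designs, and a synthetic-data generator that
    emulates the sparse species-by-chemical structure of ecotoxicological
    collections so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
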