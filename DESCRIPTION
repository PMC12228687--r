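Package: petminer
Title: Structure-Guided Enzyme Mining with Representation Trees and
    Stability Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mining enzyme candidates (e.g. PET hydrolases) from
    protein language model embeddings. Builds Ward agglomerative
    representation trees over per-protein embeddings, cuts them into clades
    and selects clades enriched in validated positives; applies a multi-tier
    screening cascade (predicted melting temperature, solubility, model
    confidence, TM-score against a reference structure, catalytic-triad
    conservation); benchmarks retrieval methods per EC group by AUROC and
    average precision; and computes molecular-dynamics stability observables
    (radius of gyration, RMSF, hydrogen-bond occupancy, autocorrelation and
    lifetime, salt-bridge counts) from plain-text trajectories. Includes
    seeded synthetic-fixture generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    bio3d,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
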