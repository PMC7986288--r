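Package: mbrascreen
Title: Screening Analysis of Compound Perturbations in Ex Vivo Gut
    Microbiota Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal screens of compound effects on
    a human gut microbiota cultured in a multi-chamber minibioreactor array
    (MBRA). Implements alpha and beta diversity metrics (Jaccard,
    Bray-Curtis, weighted and unweighted UniFrac, Pielou evenness, observed
    features), per-time-point distance-to-control trajectories with
    control and baseline normalization, phase-windowed trapezoid
    area-under-curve statistics with above/below-baseline decomposition,
    qPCR and TLR4/TLR5 reporter-assay quantification via standard curves,
    metatranscriptome read quality filtering and volcano classification,
    one-way ANOVA with Bonferroni many-to-one comparisons, reversibility
    classification, and impact ranking. Includes a synthetic MBRA
    experiment generator with configurable, optionally reversible treatment
    effects and a machine-readable answer key, so the complete pipeline can
    be exercised and validated without access to sequencing archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    S4Vectors,
    biomformat,
    phangorn,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
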