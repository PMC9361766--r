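Package: microguilds
Title: Co-Abundance Guilds and Aging-Trajectory Signatures for Gut Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for three-generation gut
    microbiome cohort studies. From a taxa-by-sample count table and sample
    metadata it estimates SparCC basis correlations from compositional counts,
    detects co-abundance guilds by Ward clustering of the 1-rho distance with
    PERMANOVA-guided tree division, builds per-age-group Spearman co-occurrence
    networks and their discrepancy metrics (shared/specific edges, closeness and
    eigenvector centralities), classifies per-taxon aging trajectories
    (rejuvenation, centenarian-specific, monotone, stable) with bootstrap
    confirmation of differential abundance, identifies family-stable species,
    and associates taxa with continuous host variables. A synthetic-cohort
    generator with planted guilds, trajectory signatures, family effects and
    host covariates makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
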