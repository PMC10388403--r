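Package: urbanphylo
Title: Phylogenetic Signal and Trait-Abundance Models for Urban Remnant Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for woody-plant functional traits in urban
    remnant forest patches. Classifies forest patches along an urbanization
    gradient from impervious-surface cover, partitions species into
    urban/rural/general/middle occupancy groups, quantifies the phylogenetic
    signal of continuous functional traits with Blomberg's K and a
    tip-shuffling permutation null, and contrasts ordinary generalized least
    squares with phylogenetic generalized least squares (Brownian-motion
    covariance) regressions of species abundance on traits. Includes a
    synthetic-data generator (pure-birth trees, Brownian traits with tunable
    signal, stratified occupancy and negative-binomial abundance) so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    nlme,
    jsonlite
Config/testthat/edition: 3
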