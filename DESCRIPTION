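Package: metafoot
Title: Enzyme-Centric Metabolic Footprint Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a curated, direction-resolved metabolic reaction
    network into a forest of enzyme-rooted shortest-path trees, assigns
    signed distance-decayed ("dissipation") weights to every metabolite
    upstream or downstream of every enzyme, and scores those footprints
    against differential metabolomics t-statistics to expose imbalance
    between an enzyme's substrates and products. Includes the supporting
    metabolomics statistics (total-ion-count normalization, QC relative
    standard deviation filtering, batch regression, empirical-Bayes
    moderated t-statistics, Benjamini-Hochberg correction), deterministic
    synthetic-data generators with planted ground truth, and a
    reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
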