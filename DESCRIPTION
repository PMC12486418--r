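Package: halocline
Title: Microbial Community Assembly and Co-Occurrence Analysis Along
    Salinity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream community-ecology analysis of amplicon count
    tables from salinity-gradient designs: rarefaction and table
    manipulation, alpha-diversity estimators (Shannon, Simpson dominance,
    Chao1, ACE, Good's coverage), Bray-Curtis ordination with PERMANOVA
    and UPGMA clustering, core-microbiome detection, Sloan neutral
    community model fitting, null-model normalized stochasticity ratios,
    Levins niche breadth, and ensemble co-occurrence network inference
    with permutation nulls, bootstrap restoration, Brown p-value merging
    and Benjamini-Hochberg control. Includes seeded generators for
    neutral, environmentally filtered and correlation-planted synthetic
    communities, and a pipeline runner that chains every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
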