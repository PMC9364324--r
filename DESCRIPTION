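Package: nanosorb
Title: Predicting Adsorption Affinities of Small Biomolecules to Engineered
    Nanomaterials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting the adsorption affinity
    (log k) of enteric microbial metabolites to metal and carbon engineered
    nanomaterials. Implements the biological surface adsorption index (BSAI)
    linear free-energy relationship over Abraham solvation descriptors,
    construction of secondary descriptor-based QSAR models by forward-selection
    multiple linear regression under a variance-inflation-factor constraint,
    applicability-domain analysis (Insubria graphs, Williams plots, and an
    ordination-centroid domain), nanomaterial comparison statistics (Bray-Curtis
    dissimilarity, distance-based redundancy analysis with marginal permutation
    tests, Kruskal-Wallis with Dunn/Holm post hoc tests), and calculation of
    adsorption affinities from potential-of-mean-force profiles by Boltzmann
    integration. Ships a curated metabolite inventory, the frozen per-material
    QSAR equations, and seeded synthetic-data generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    vegan,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
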