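Package: ternet
Title: Edge-Colored Bipartite Drug-Target Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build and analyse drug-target interaction data as edge-colored
    bipartite networks in which every drug-target pair is active, inactive,
    or of unknown activity status. Provides ternary network construction
    from activity records or files (edge lists, status matrices), activity
    classification against a potency threshold, decomposition into active,
    inactive and unknown biadjacency matrices, polypharmacology and
    polyspecificity degrees and their transpose duality, per-entity
    interaction profile vectors with distances and similarities, global and
    local measures of data completeness, lower and upper bounds on the true
    degrees under missing data, GraphML export, and seeded generators of
    synthetic ground-truth and database-style incomplete networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    igraph,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
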