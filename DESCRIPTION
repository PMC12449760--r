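Package: paleonet
Title: Temporal Change in Taxon Co-Occurrence Networks from Assemblage Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds Spearman-correlation co-occurrence networks from
    sample-by-taxon assemblage count matrices (lake-sediment subfossil
    records and similar community time series), computes connectance,
    modularity (via edge-betweenness community detection), mean degree
    centrality and degree-distribution skewness, delineates temporal zones
    in stratigraphic records by constrained incremental sum-of-squares
    clustering with broken-stick validation, and tests metric shifts
    between periods or zones against constrained Erdos-Renyi null
    ensembles together with rarefied Shannon-diversity comparisons.
    Includes a synthetic assemblage generator with planted association
    structure and change points for end-to-end validation.
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
    utils,
    vegan
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
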