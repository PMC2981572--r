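Package: enrichmapr
Title: Enrichment Map Networks for Gene-Set Enrichment Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns gene-set enrichment results into a similarity network of
    gene-sets (an "enrichment map"): nodes are significantly enriched
    gene-sets, edges connect sets whose Jaccard or overlap coefficient passes
    a threshold, node colour encodes signed enrichment significance, and a
    weighted force-directed layout groups redundant sets into visual clusters.
    Reads GMT gene-set collections, GSEA report tables or generic enrichment
    tables, and GCT/CLS expression data; supports two-dataset comparison maps,
    Fisher's exact query-set post-analysis, heat-map data extraction, and
    GraphML/SIF/TSV export. Includes a synthetic-data generator with planted
    cluster structure and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
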