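Package: topoqspr
Title: Distance-Based Topological Indices and QSPR Models for Tricyclic
    Antidepressant Drugs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes five distance-based topological indices (Wiener,
    hyper-Wiener, Harary, detour and detour-Harary) on hydrogen-depleted
    molecular graphs, including an exact detour (longest simple path) engine
    built on block-cut-tree decomposition, and fits simple linear QSPR models
    relating the indices to physicochemical properties.  Ships the molecular
    structures, property table and published index table for fifteen tricyclic
    antidepressant drugs, a synthetic-data generator for property-based
    testing, and command-line style report writers (CSV and JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
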