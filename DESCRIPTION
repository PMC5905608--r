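Package: asbscaffolds
Title: Analog Series-Based Scaffold Extraction from Compound Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts analog series from compound collections via
    size-restricted, retrosynthetically fragmented matched molecular pairs
    (RECAP-MMPs), derives one analog series-based (ASB) scaffold per series
    with one or multiple numbered substitution sites, annotates scaffolds
    with target and compound-class information, merges and deduplicates
    scaffold collections across sources, and writes ranked, deposition-style
    scaffold tables. Includes a synthetic combinatorial-library generator
    with known ground-truth scaffolds for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    utils,
    stats,
    tools,
    igraph,
    xml2,
    yaml,
    jsonlite,
    withr,
    ChemmineOB,
    ChemmineR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'obabel.R'
    'mol-graph.R'
    'chem-io.R'
    'fragmentation.R'
    'mmp-index.R'
    'series-extraction.R'
    'scaffold-derivation.R'
    'annotation-stats.R'
    'synthetic-fixtures.R'
    'pipeline.R'
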