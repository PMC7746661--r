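Package: hostbreadth
Title: Food-Plant Breadth and Phylogenetic Polyphagy Scores for
    Caterpillar Host Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assemble a qualitative caterpillar food-plant
    dataset from multiple overlapping record sources and to quantify
    the polyphagy of the moths involved. Source record tables are read,
    name-normalised, resolved against local plant and moth taxonomies,
    deduplicated on the (moth species, plant identity, source, setting)
    key and partitioned into wild and captive observations. Per-species
    and per-genus food-plant breadth summaries are built at plant genus,
    species, family and order ranks, and a polyphagy score is computed
    as Faith's phylogenetic diversity of the angiosperm plant families
    eaten in the wild, on a user-supplied dated family-level phylogeny,
    averaged over species within each moth genus. A synthetic-data
    generator with full ground-truth bookkeeping makes every pipeline
    stage testable without access to the original source databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    readr,
    readxl,
    rlang,
    stats,
    stringr,
    tibble,
    tools
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
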