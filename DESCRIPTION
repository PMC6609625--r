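Package: milkatlas
Title: Presence/Absence Meta-Analysis of the Bovine Milk Proteome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates protein identification lists from multiple bovine
    milk proteomics datasets into a presence/absence atlas keyed by gene
    name. Harmonizes heterogeneous protein identifiers to gene symbols via
    mapping tables, classifies datasets into milk fractions (skimmed, whey,
    milk fat globule membrane, exosomes) from their isolation protocol and
    into lactation stages (colostrum, early, peak, mid, drying-off) from
    days in milk, decomposes category sets into exact Venn regions to find
    category-exclusive proteins, performs hypergeometric over-representation
    tests with Benjamini-Hochberg correction against flat annotation tables
    (Gene Ontology, subcellular location, protein complexes), and
    cross-references candidate biomarkers against tissue proteome lists and
    curated evidence flags. A seeded simulator generates multi-dataset
    detection lists with known ground truth (shared core, planted
    category-exclusive sets, detection dropout, identifier noise) so every
    pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
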