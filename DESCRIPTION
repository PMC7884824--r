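Package: netpharm
Title: Network Pharmacology of Herbal Extracts: MS Annotation, Target
    Transfer, Hub Filtering and Pathway Enrichment
Version: 0.1.0
Authors@R: person("netpharm", "developers", role = c("aut", "cre"),
    email = "netpharm@example.org")
Description: An integrative network-pharmacology pipeline for
    multi-component herbal medicines. Annotates LC-MS peak tables against
    a compound library by monoisotopic adduct m/z within a ppm tolerance,
    assigns MS2 neutral losses, transfers approved-drug targets to
    compounds by Tanimoto fingerprint similarity, builds the putative
    target / disease gene interaction network from confidence-scored
    edges, selects hub and major-hub genes by median-based topological
    filters (degree, betweenness, closeness), performs hypergeometric
    pathway over-representation on GMT gene sets, and quantifies qPCR
    validation experiments with the 2^-ddCt method. Seeded synthetic-data
    generators with planted structure provide known-answer tests for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
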