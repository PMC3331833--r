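Package: polyqscreen
Title: Network-Boosted Analysis of RNAi Modifier Screens for
    Polyglutamine Neuron Dysfunction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scoring and network-boosted analysis of large-scale RNAi
    modifier screens of the kind used to probe polyglutamine-induced
    neuron dysfunction in C. elegans touch receptor neurons. Converts
    per-animal touch-test records into S-scores and hit calls against an
    empty-vector baseline, performs hypergeometric gene-set enrichment
    with Gene Ontology true-path propagation, smooths the S-score signal
    over a weighted functional gene network by graph-Laplacian spectral
    low-pass filtering (40 attenuations removing the highest-frequency
    2.5 percent of components at a time), extracts signed gene modules
    with birth-level, stability and redundancy filters, and intersects
    conserved modifier genes with mouse striatal dysregulation tables.
    A seeded synthetic-data generator emulates the screen geometry and a
    planted-partition gene network so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
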