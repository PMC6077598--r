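Package: netpharm
Title: Systems Pharmacology and Network Analysis for Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated systems-pharmacology and bioinformatics pipeline
    for dissecting the polypharmacology of multi-herb formulas. Screens
    herbal compound libraries into active ingredients by oral bioavailability
    and Tanimoto drug-likeness, assembles compound-target and
    protein-protein interaction networks, computes NetworkAnalyzer-style
    topology reports and centrality-based hub screening, performs
    hypergeometric over-representation analysis of pathway gene sets with
    Benjamini-Hochberg adjustment, and mines cancer-genomics alteration
    matrices (OncoPrint ordering, mutual-exclusivity tests, Kaplan-Meier and
    log-rank survival comparison of altered versus unaltered cases). Seeded
    synthetic-data generators emulate every input so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
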