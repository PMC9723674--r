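Package: ecoassembly
Title: Null-Model Inference of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the relative importance of selection, dispersal and
    drift in structuring microbial communities from phylogenetic and
    compositional turnover. Implements abundance-weighted beta mean nearest
    taxon distance (betaMNTD), the taxa-shuffle null and the beta nearest
    taxon index (betaNTI), the Raup-Crick null on Bray-Curtis dissimilarity
    (RC-Bray), classification of sample pairs into five assembly processes,
    group comparisons of process proportions (two-proportion Z-tests,
    Kruskal-Wallis), a Mantel-correlogram check of phylogenetic niche
    conservatism, and distance-based redundancy analysis with two-set
    variation partitioning of betaNTI matrices into soil and vegetation
    fractions. Includes a synthetic-data generator that emulates a paired
    reference/disturbed watershed design with known assembly regimes, so the
    whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    vegan,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
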