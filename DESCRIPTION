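Package: ploidysig
Title: Cross-Species Extraction of Conserved Polyploidy-Associated
    Transcriptional Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reciprocal cross-species differential expression with
    direction-concordance intersection, correlation-matrix principal
    component analysis with factor-labelled components and SD-score gene
    selection, interactome binomial enrichment with double-background
    gene-set over-representation (Storey q-values), and high-stringency
    interaction-network construction with Markov clustering. Includes a
    synthetic-data generator that emulates the statistical structure of
    polyploid versus diploid tissue transcriptomes (shared, tissue,
    species and ploidy components) with planted ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
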