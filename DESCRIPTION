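Package: metlocal
Title: Network Locality Scoring for Matched Metabolome-Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrative analysis of matched untargeted metabolomics and
    transcriptomics cohorts, built around a network-based "locality score"
    that identifies metabolic enzymes whose expression change leaves a
    functional footprint on proximal metabolites. Provides exact-mass ion
    annotation for negative-mode flow-injection data, quantile
    normalization, age-correlation and two-group differential statistics
    with Storey q-value and Benjamini-Hochberg control, a recursive
    nested-subset hypergeometric pathway enrichment, enzyme-metabolite
    network distances on a reaction-pair graph, a distance-matrix
    permutation test for locality scores, and a synthetic matched-omics
    generator with planted, network-localized age effects for end-to-end
    validation.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
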