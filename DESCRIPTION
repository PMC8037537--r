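Package: cernaweaver
Title: Competing Endogenous RNA Network Analysis for the Ciona robusta Pharynx Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for competing endogenous RNA (ceRNA) analysis of
    the Ciona robusta pharynx transcriptome: transcript biotype census,
    pseudogene-to-parent identity, microRNA cataloguing with seed families and
    E-value gated precursor annotation, self-organizing-map based miRNA target
    prediction with a nearest-neighbor duplex free-energy filter, Fisher/EASE/
    Benjamini term enrichment, 3'UTR cis-element scanning, and construction of
    miRNA-mRNA-pseudogene networks with ceRNA couples. Ships a synthetic
    transcriptome generator with planted ground truth so every stage is testable
    without external downloads, plus transcriptions of the study's summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
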