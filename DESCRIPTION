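Package: rivitseq
Title: Sigma-Factor Regulon Reconstruction from In Vitro Transcription
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls transcription start sites (TSSs) from 5'-end read-count
    tracks of in vitro transcription reactions, normalizes samples against
    ERCC spike-in controls, tests per-gene differential transcription
    between a sigma-factor reaction and a no-sigma-factor control with a
    negative-binomial Wald test, integrates sigma-dependent TSSs with
    upregulated genes into direct and operon-extended target sets, prepares
    promoter windows for motif discovery and filters motif-discovery
    output, and assembles sigma-factor regulatory networks and pairwise
    crosstalk matrices. Ships a fully specified synthetic-data generator
    (genome, annotation, restriction-fragment-end background, spike-ins)
    with known ground truth so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    xml2,
    igraph,
    BiocGenerics,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
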