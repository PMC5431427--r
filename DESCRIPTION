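Package: spadix
Title: Organ-Resolved Transcriptome Co-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packages", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for organ-resolved bulk RNA-seq analysis:
    TMM scaling factors and FPKM/log-CPM normalization, permutation F-test
    differential expression across organs with Benjamini-Hochberg FDR control,
    an organ presence/absence expression atlas with Venn partitions and
    organ-exclusive gene sets, a signed weighted gene co-expression network
    with topological overlap, module detection and eigengene merging, network
    sparsification for export, and a transcription-factor mining procedure
    that nominates candidate regulators of pathway genes. Ships a
    negative-binomial multi-organ count simulator with planted co-expression
    modules and regulator-target links so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
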