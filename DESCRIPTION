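Package: rrsnp
Title: Diagnostic SNP Discovery from Reduced-Representation Sequencing
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates genome-reduced, barcode-multiplexed 454-style
    pyrosequencing experiments across multiple diverged lineages, and
    implements a counts-based pipeline for discovering lineage-diagnostic
    (autapomorphic) single nucleotide polymorphisms from read pileups:
    in-silico double restriction digestion and size selection, MID-barcode
    demultiplexing, per-individual allele counting, a seven-criterion
    diagnostic SNP filter with a position-weighted window screen for
    misassembled or paralogous regions, and downstream panel evaluation
    (per-group minor allele frequencies, allele-sharing distances,
    principal coordinates analysis, and a diagnostic-allele admixture
    index for hybrid flagging).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
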