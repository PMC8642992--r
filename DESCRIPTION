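Package: circorf
Title: Discovery and Validation Design for Protein-Coding Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, simulation-backed pipeline for identifying
    protein-coding circular RNAs (circRNAs) from back-splice junction (BSJ)
    calls. Classifies BSJ events against a gene annotation into five genomic
    categories, reconstructs full-length circular sequences, counts
    junction-spanning reads and normalizes them to TPM, screens paired
    tumor/normal designs with fold-change, significance and recurrence
    filters, enumerates junction-spanning and rolling-circle open reading
    frames on circular templates, scans for IRES-like elements, and emits
    junction-specific validation designs: FLAG-tagged constructs, start-codon
    mutants, divergent primers, junction siRNAs, distinguishing tryptic
    peptides and TCF motif scans. Includes a fully deterministic synthetic
    data generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
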