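Package: scisokit
Title: Single-Cell Long-Read Isoform Discovery, Classification and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a single-cell
    hybrid short/long-read isoform discovery workflow: full-length
    non-chimeric (FLNC) read extraction with cell-barcode correction and UMI
    deduplication, splice-junction-chain collapse into unique isoforms,
    SQANTI-style structural classification (FSM/ISM/NIC/NNC) with CAGE/polyA
    end-support and junction-artifact filtering, local alternative-splicing
    event detection (ES/A5/A3/AF/AL/RI/MX), ORF prediction with proteogenomic
    peptide support, short-read junction validation, and per-cell isoform
    matrices with cell-type-specificity summaries. Ships a deterministic
    synthetic-experiment generator with a ground-truth manifest so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    data.table,
    Matrix,
    jsonlite,
    Biostrings,
    GenomicAlignments,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
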