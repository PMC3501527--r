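Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis of tag-based digital gene expression
    (SAGE/DGE) libraries: in-silico NlaIII/MmeI restriction-tag extraction
    from a reference transcriptome (every CATG site plus 17 downstream
    bases), raw-tag cleaning (adapter-only, N-containing and
    copy-number-1 reads), tag-to-gene mapping permitting at most one base
    mismatch, transcripts-per-million normalization, differential
    expression between two libraries by the Audic-Claverie exact test
    with Benjamini-Hochberg false discovery rate control, and
    hypergeometric term enrichment of the resulting gene sets. Includes a
    synthetic-data generator with known expression truth so every stage
    can be validated without sequencing data, plus a delta-delta-Ct
    utility for qRT-PCR fold changes.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
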