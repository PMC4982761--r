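Package: readthru
Title: Detection of Transcription Read-Through and 3'UTR Lengthening from Strand-Specific RNA-seq
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transcription read-through downstream of annotated
    transcription termination sites from strand-specific RNA-seq signal and
    classifies genes whose long-3'UTR (alternative polyadenylation) isoform
    usage changes between two conditions. Provides FPKM-based expression
    tiering, read-through fold-change calling with overlap exclusion,
    50-bp binned and body-scaled metagene profiles, TSS/TTS-centred heatmap
    matrices, and the accompanying statistical tests (two-sample
    Kolmogorov-Smirnov, exact Fisher on small contingency tables, Pearson
    co-occupancy correlation with average-linkage ordering, Welch t-test).
    Ships a synthetic-data generator producing annotation, stranded tag
    libraries, ChIP-like tracks and a ground-truth table so the entire
    pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
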