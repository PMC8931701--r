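Package: erfscan
Title: Classification and Regulatory Analysis of Plant ERF/DREB Transcription Factors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of the single-AP2-domain ERF and
    DREB transcription-factor subfamilies. Provides post-HMM-search candidate
    filtering, diagnostic-residue extraction from AP2 domains with
    model-coordinate calibration, residue-based DREB/ERF subfamily
    classification, DRE/CRT versus GCC-box binding-capability prediction,
    EAR (LxLxL, DLNxxP) and EDLL protein-motif detection with composite
    repressor typing, double-stranded promoter cis-element scanning (AuxRE,
    DRE/CRT, GCC box) with overlap and cluster detection, TPM expression-trend
    classification across developmental phases, delta-delta-Ct relative
    expression, and a decision procedure inferring direct or indirect
    auxin/ethylene regulation. Includes a synthetic-data generator that plants
    machine-readable ground truth in proteins, promoters and expression
    matrices so every stage can be validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
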