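Package: CMannoScan
Title: Candidate C-Mannosylated Proteins from Quantitative Secretomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for discovering candidate tryptophan C-mannosylated
    proteins from label-free quantitative secretomics of glycosyltransferase
    knockout versus wild-type cell lines. Implements WxxW/WxxC consensus-site
    and thrombospondin type 1 repeat (TSR) motif scanning of protein
    databases, Perseus-style filtering and left-shifted normal imputation of
    MaxQuant protein-group LFQ tables, per-protein Student t tests with
    per-clone fold changes, Fisher exact Pfam domain enrichment against the
    filtered secretome background, glycopeptide mass-ladder enumeration
    (C-mannose and O-fucose/fucose-glucose glycoforms), extracted-ion-
    chromatogram annotation and relative glycoform quantification from MS1
    centroid runs, and enumeration and scheduling of MRM transitions.
    Synthetic-data generators with recorded ground truth allow every stage to
    be exercised end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
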