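Package: phylofoot
Title: Phylogenetic Footprinting of Conserved Transcription-Factor
    Binding Sites in Multi-Species Promoter Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects conserved non-coding sequences (CNCSs) in upstream
    regions of orthologous genes across multiple species by pairwise
    global alignment and sliding-window identity, optionally gated by
    ATAC-seq open-chromatin peaks; scans each species' CNCS with
    position weight matrices under a relative-score (deficit)
    threshold; retains motif occurrences found in every species at the
    same length-normalized position within a configurable margin; and
    gates the surviving candidates by bulk and pseudobulk single-cell
    expression percentiles of the corresponding transcription-factor
    genes. Also provides macrosynteny chromosome-correspondence
    statistics from homology-hit tables via C-score filtering and
    one-sided Fisher exact tests with Bonferroni correction, and a
    synthetic-data generator with full ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
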