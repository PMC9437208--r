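Package: tritarget
Title: Dysregulation of Endogenous Trinucleotide-Repeat-Bearing Genes in
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects transcriptome-wide dysregulation of genes whose
    transcripts carry endogenous trinucleotide repeat runs (e.g. CTG/CAG),
    the putative targets of repeat-derived small interfering RNAs in
    myotonic dystrophy type 1.  Provides a mismatch-tolerant tandem-repeat
    scanner for transcript FASTA, a TMM/log-CPM moderated-t differential
    expression workflow, observed/expected repeat-gene enrichment grids
    with Fisher exact tests across motifs, repeat lengths and fold-change
    thresholds, Kolmogorov-Smirnov rank tests for repeat-bearing
    transcription factors, regulatory-network coverage, cross-cohort
    overlap statistics, per-gene phenotype correlation, and a fully
    parameterised negative-binomial cohort simulator with planted
    repeat-gene silencing for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    edgeR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
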