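Package: tfsig
Title: Transcription Factor Motif Signatures for Aging Phenotype Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis of transcription factor (TF) regulation from trimmed
    differential-expression gene lists. Scans promoter windows with JASPAR and
    TRANSFAC position weight matrices using a best-hit (PSCAN-style) statistic,
    scores per-sample motif over- and under-representation with a z-test against
    a genomic background and Benjamini-Hochberg FDR control, assembles filtered
    rank signatures across samples, groups samples by Spearman complete-linkage
    clustering, k-means and PCA, screens motifs with a multiclass SAM statistic,
    detects motifs that switch between enrichment and avoidance across two
    phenotypes, and probes stress-sensor connectivity in a seeded minimum
    protein-interaction network. Includes a synthetic-data generator that plants
    motifs and network modules with known ground truth so every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
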