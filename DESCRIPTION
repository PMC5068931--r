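Package: transeval
Title: Evaluation of De Novo Transcriptome Assemblies and Expression Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based and reference-free quality metrics for de novo
    transcriptome assemblies, together with the expression-quantification
    arithmetic used alongside them. Computes contig length statistics and N50,
    removes redundant (identical or contained) contigs, derives the Ortholog
    Hit Ratio and threshold-based completeness and contiguity from tabular
    alignment hit tables, detects and cuts chimeric contigs, converts fragment
    counts to FPKM, fits qPCR calibration curves and efficiency-corrected
    relative expression ratios with calibrator correction, and estimates
    pairwise Ka/Ks by the Nei-Gojobori method with Jukes-Cantor correction.
    Ships synthetic-data generators with attached ground truth so every stage
    is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    broom,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
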