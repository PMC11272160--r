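Package: amniowave
Title: Temporal Wave Classification and Atlas Projection for Time-Course RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for BMP4-driven time-course bulk RNA-seq of
    human pluripotent stem cell derived amnion. Provides count-matrix I/O and
    gene filtering, median-of-ratios normalization, consecutive-timepoint
    differential expression with Benjamini-Hochberg FDR, classification of
    upregulated genes into temporal activation waves (immediate, early,
    intermediate-1, intermediate-2, late), and projection of bulk samples onto
    an annotated single-cell reference atlas via pseudo-single-cell
    downsampling, TF-IDF/LSI embedding transfer and medoid nearest-cell label
    assignment. Includes a negative-binomial synthetic-data generator with
    planted ground truth so every stage is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    limma,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
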