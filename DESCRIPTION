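Package: splicemir
Title: Escape from miRNA Regulation Through Alternative Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcriptome-scale inference of whether alternative splicing
    lets transcript isoforms escape miRNA regulation via target sites in
    coding regions. Classifies (miRNA, transcript) pairs by predicted
    binding location, filters miRNA-gene pairs by expression, splicing
    structure and correlation, fits nested ordinary-least-squares models
    (full vs. reduced) per pair under three settings, and compares
    subsampled significance-ratio distributions against a within-gene
    binding-label permutation null. Includes a synthetic-data generator
    with known ground truth for calibration and power analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer,
    withr
Config/testthat/edition: 3
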