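Package: ddpheno
Title: Data-Driven RNA Phenotypes from Base-Level Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-sample base-level RNA-seq coverage (bigWig) into
    per-gene orthogonal latent phenotypes suitable for cis-QTL mapping and
    TWAS. Gene regions are segmented into variance-adaptive coverage bins,
    binned coverage is depth-scaled and log-transformed, and a principal
    component model is fitted per gene; sample projections onto the retained
    components are the data-driven phenotypes (DDPs). An optional
    residualization pathway regresses knowledge-driven phenotypes (expression,
    splicing ratios, etc.) out of each bin feature before PCA, yielding
    residual phenotypes (rDDPs) that complement annotation-based quantifiers.
    Includes a synthetic-data generator (isoform-mixture coverage with known
    latent factors, Poisson noise and per-sample depth multipliers) so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
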