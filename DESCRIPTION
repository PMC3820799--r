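Package: rddmr
Title: CHH Hypomethylation DMR Calling and Multi-Assay Integration for
    RNA-Directed DNA Methylation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls CHH-context hypomethylated regions (DMRs) from
    per-cytosine bisulfite count tables by kernel smoothing, a signed
    site-level statistic with wild-type replicate variance estimation,
    segmentation, and an explicit filter cascade (site count, mean raw
    methylation difference, area statistic). Integrates the resulting
    regions with H3K4 di-/trimethylation ChIP-seq density, 24-nt siRNA
    abundance and mRNA expression through window and scaled-metaplot
    quantification with duplicate-read collapsing and unique-read RPKM.
    Includes a seeded synthetic-data generator (genome, replicate
    methylomes with implanted hypomethylated regions, annotation, read
    sets) with a machine-readable truth record for recovery testing, and
    a single-call pipeline with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    data.table,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
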