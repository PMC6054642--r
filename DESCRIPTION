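Package: chipexosim
Title: Simulation and Diagnostics for ChIP-exo Protocol Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A mechanistic paired-end read simulator for ChIP-based
    protocol variants (ChIP-seq, ChIPmentation, ChIP-exo 1.1/3.1/4.0/4.1/5.0
    and ChIP-nexus) together with the diagnostics used to compare them:
    synthetic genomes with controlled base composition and planted motif
    sites, lambda-exonuclease stop-site geometry with shouldering, Tn5
    tagmentation with sequence preference and carryover, ChIP-nexus barcode
    construction and over-trimming, PCR duplication; and on the analysis
    side, duplicate removal, 5'-end nucleotide-frequency profiling with
    IUPAC bias calling, barcode quality control, insert-size statistics,
    and strand-separated motif-anchored profiling (heatmap matrices, linked
    row sorting, composites, stop-site peaks, peak shifts, shoulder
    fraction and strand segregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
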