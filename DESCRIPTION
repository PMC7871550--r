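Package: xqtlmap
Title: Bulk-Segregant X-QTL Mapping and Backcross Introgression Analysis
    for Yeast Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extreme-QTL (X-QTL) bulk-segregant analysis for a two-parent
    haploid yeast cross: per-SNV parental allele ratios from pooled
    whole-genome sequencing, windowed median tracks, selected-minus-average
    difference tracks and QTL peak calling; microplate Nile Red phenotyping
    (cell-density normalization, plate-reference scaling, 100-bin log2
    frequency distributions, transgressive-segregation fractions); a
    7-generation backcross driver with parental-origin haplotype-block
    inference from consecutive SNV calls, retained donor-genome
    quantification against the (1/2)^g expectation, and duplicated-segment
    detection from windowed sequencing depth. A synthetic cross generator
    (meiosis under a genetic map, haploid selection markers, polygenic trait
    model, FACS gating, pooled allele-count sequencing) exercises every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    data.table,
    jsonlite,
    yaml,
    rlang,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
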