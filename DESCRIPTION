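Package: polyeqtl
Title: eQTL Mapping, Hotspot Detection and Regulatory Network Ranking for Allopolyploid Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of population-scale expression QTL studies in
    allotetraploid crops with An/Cn subgenomes. Provides a per-gene association
    scan with LD clumping and local/distant classification, permutation-based
    detection of distant-eQTL hotspots, adjacency (expression piggybacking)
    analysis of genes with local eQTLs, homoeolog pairing by reciprocal best
    hit with regulation-direction and feedback analysis, open-chromatin
    enrichment tests for eQTL lead SNPs, transcriptome-wide association with
    FDR control, and gradient-boosted-tree ranking of candidate upstream
    transcription factors. Includes a synthetic-study generator with planted
    ground truth for power and calibration analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    vcfR,
    IRanges,
    GenomicRanges,
    rtracklayer,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
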