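Package: mirforge
Title: IsomiR Characterization and Sequencing-Error-Aware Small RNA Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing microRNA sequence variants (isomiRs) in
    small RNA sequencing data. Estimates position-class erroneous sequence
    variant (ESV) rates from reads aligned to abundant control RNAs, derives
    count thresholds that separate genuine isomiRs and allelic variants from
    pipeline artifacts, classifies reads against canonical mature miRNAs with
    a seed-anchored aligner, resolves templated versus non-templated variants
    using genomic context, validates novel miRNA candidates against
    hairpin-folding and read-evidence criteria, annotates miRNA gene clusters,
    predicts seed-complementary target sites in 3'UTR sets with a simplified
    nearest-neighbor duplex model, and summarizes tissue and developmental
    expression (RPM normalization, enrichment classification, delta-delta-Ct
    qPCR analysis). Includes a synthetic small-RNA library generator with a
    ground-truth manifest so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
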