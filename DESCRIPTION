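Package: phasir
Title: Phased siRNA Detection and Locus-Scale Small RNA Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of deep-sequenced small RNAs mapped to a single
    annotated gene locus: 3' adapter trimming and collapsing of reads into
    unique siRNA species, perfect-match placement on both strands of the
    reference, strand-resolved size distributions and per-position abundance
    tracks, feature confinement and intron-exon boundary statistics,
    allele-discriminating classification against a second reference,
    cross-sample abundance-rank commonality (top-N overlap and Spearman rank
    correlation with an abundance filter), and phased siRNA analysis in all
    21 registers of both strands (occupancy, maximal contiguous-unit region
    calling, Howell-style phasing scores, and cross-sample conservation of
    region ends). Includes a fully seeded synthetic small RNA library
    generator with ground-truth bookkeeping and a config-driven pipeline
    that orchestrates the whole analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
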