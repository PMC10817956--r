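Package: sweepscan
Title: Selection-Signature Scanning and Diversity Analysis for Multi-Population SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate selective sweeps in multi-population diploid SNP
    data. From a phased multi-sample VCF the package applies genotype- and
    site-level quality filters (genotype quality, depth, missingness, minor
    allele frequency, Hardy-Weinberg exact test, relatedness-based sample
    removal), computes windowed nucleotide diversity, per-sample inbreeding,
    Weir-Cockerham windowed weighted Fst, linkage-disequilibrium decay and
    pruning, and principal components, and runs three sliding-window selection
    scans: pooled heterozygosity (ZHp), standardized windowed Fst (ZFst), and
    window-mean standardized cross-population extended haplotype homozygosity
    (XP-EHH). Candidate windows are called by empirical P-value, fixed Z
    thresholds and an XP-EHH directionality rule, intersected across scans,
    merged into regions, and annotated against gene models. A forward-in-time
    Wright-Fisher simulator with recombination, migration and planted additive
    sweeps generates phased multi-population panels with ground truth so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pracma,
    optparse
Config/testthat/edition: 3
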