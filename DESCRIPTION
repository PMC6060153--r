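Package: chromQTL
Title: Histone QTL Mapping, Risk-Haplotype Enrichment and Chromatin-Network
    Interaction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for mapping histone quantitative trait loci (hQTLs)
    from allele-specific ChIP-seq read counts and relating them to gene
    expression through chromatin topology. Builds population consensus
    enhancer peak maps from per-individual peak calls; tests variants for
    allelic imbalance with a combined haplotype test (joint beta-binomial /
    negative-binomial likelihood ratio test) with Holm family-wise error
    control and permutation calibration; measures enrichment of hQTLs on
    risk haplotypes by matched-permutation sampling within minor allele
    frequency and TSS-distance categories; scans for cis-eQTLs; fits
    negative-binomial joint-effect models quantifying the expression
    variance explained (D-squared) by hQTLs within haplotype blocks; and
    classifies distal eQTL-by-hQTL interaction effects within HiChIP
    chromatin-loop networks. A synthetic-data generator reproduces the
    statistical structure of each input so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    IRanges,
    igraph,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
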