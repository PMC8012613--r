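Package: poolscan
Title: Pooled-Exome Genetic Association Scans and Insecticide Bioassay
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pool-seq genetic association studies of
    insecticide resistance. Computes per-site contingency chi-square scores
    of allele-frequency differentiation between resistant and susceptible
    mosquito pools, applies replicate-consistency and coverage filters,
    aggregates sites into depth-weighted gene-wise scores with
    Benjamini-Hochberg control, scans pre-miRNA hairpin intervals for
    associated SNPs, and tests functional categories for hypergeometric
    over-representation. Also implements the phenotype-side statistics:
    log-dose probit LC50 fits with confidence intervals, resistance ratios,
    knockdown and mortality comparisons, multi-locus genotype frequencies,
    and delta-delta-Ct relative quantitation. A seeded two-stage
    pooled-sequencing simulator generates all inputs so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
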