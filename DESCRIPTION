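Package: rvburden
Title: Weighted Rare-Variant Burden and Enrichment Analysis for
    Case-Control Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aggregate rare-variant analysis for case-control exome
    cohorts organised around a candidate gene panel. Provides variant
    filtering (capture-region intersection, genotyping-rate and
    minor-allele-frequency filters), Madsen-Browning weighted burden
    scoring with a score-test or permutation association test for binary
    phenotypes, relative case/control burden curves across MAF and
    CADD-phred cutoff grids, a Monte Carlo gene-panel null for the
    burden-trend slope, per-variant Fisher exact enrichment against a
    reference allele-frequency database with a two-stage
    enriched/population-specific classification, and a seeded synthetic
    cohort generator so that every stage can be exercised without access
    to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Matrix,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
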