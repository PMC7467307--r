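Package: mipkit
Title: Molecular Inversion Probe Panel Design, Simulation and Targeted
    Variant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of molecular inversion probe (MIP) panels for targeted
    resequencing under geometric and uniqueness constraints (arm lengths,
    gap-fill size, tiling overlap, arm copy-count and common-SNP exclusion),
    simulation of MIP capture reads with unique molecular identifiers (UMIs),
    PCR duplicates, sequencing errors and GC-dependent probe dropout, a
    read-processing core that assigns reads to probes by arm matching,
    de-duplicates molecules by UMI, computes per-base unique-molecule
    coverage and recommends probe rebalancing, a unique-molecule variant
    caller with depth, allele-fraction and cohort-frequency filters, and
    evaluation statistics for capture efficiency, truth-set sensitivity,
    cross-platform concordance, per-gene coverage reporting and a
    per-sample cost model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
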