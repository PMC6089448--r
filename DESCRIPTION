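Package: ataxmap
Title: Autozygosity Mapping and Characterization of a Recessive Bovine Ataxia Variant
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to map a recessive Mendelian disease in livestock from
    SNP-array genotypes and characterize the causal variant: runs-of-homozygosity
    detection and shared-autozygosity interval mapping tolerant of phenocopies,
    a case/control variant filtering cascade with a reverse-strand-aware coding
    consequence annotator and a splice donor position-weight-matrix scorer,
    cohort allele-frequency and homozygote-deficit statistics, a pedigree
    numerator-relationship-matrix REML mixed model for genotype-trait
    association, and paranodal-length morphometry. Includes a synthetic-data
    generator (linebred pedigrees, gene dropping, variant tables, phenotypes,
    morphometry) with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Matrix,
    Biostrings,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
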