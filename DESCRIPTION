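Package: oligotrio
Title: Anchor-Gene Oligogenic Variant Prioritisation from Family Exome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for investigating oligogenic (digenic) inheritance in rare
    disease families whose index cases carry a variant in a single anchor gene,
    such as NR5A1/SF-1 in 46,XY differences of sex development (DSD). The
    package ingests multi-sample VCF, pedigree (PED) and annotation sidecar
    tables, applies a rare-variant filter cascade (read depth, consequence,
    karyotype-aware gnomAD allele frequency, gene panel), aggregates in-silico
    predictor calls and ACMG classes into a per-variant consensus, pairs
    surviving candidates with the family anchor variant under
    pair-pathogenicity score thresholds, classifies inheritance and
    co-segregation within families, and summarises variant and gene recurrence
    across a cohort. A synthetic cohort generator with a digenic penetrance
    model provides planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
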