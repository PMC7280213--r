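Package: gradh2
Title: Spatial Marker Gradients, Partitioned SNP Heritability, and
    Polygenic Risk for Regional Brain Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links spatial transcription of inhibitory interneuron marker
    genes (somatostatin, parvalbumin) to heritable regional brain phenotypes
    and psychiatric polygenic risk.  Provides marker-difference maps with
    gene-wise and two-gene correlation-null AUC statistics, cell-type
    deconvolution of bulk expression by non-negative least squares on
    single-cell signatures, guilt-by-association gene-set nomination with
    SNP-window partitioning, multi-partition average-information REML
    estimation of partitioned SNP heritability with a half-half chi-square
    mixture Wald test and a partition enrichment statistic, clump-and-threshold
    polygenic scoring with an MHC top-SNP rule, competitive gene-set trend
    tests against GWAS summary statistics, and a synthetic-data generator
    emulating the statistical structure of every input so the full pipeline
    is testable offline with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    IRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    jsonlite
Config/testthat/edition: 3
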