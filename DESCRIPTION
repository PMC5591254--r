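Package: wntscreen
Title: Single-Cell Pathway Activity Inference and Amplification Coverage QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint phenotype-plus-genotype analysis of single tumour cells.
    Infers transcriptional pathway activity (the canonical Wnt program by
    default) from gene expression with a three-layer Bayesian network
    (transcription complex, target genes, expression measurements) using
    calibrated per-gene thresholds and soft virtual evidence; quantifies
    whole-genome-amplification coverage uniformity with Lorenz curves,
    coverage-depth profiles and Gini coefficients; screens per-cell variant
    calls against a driver-mutation panel with a genome-breadth gate; and
    ships a synthetic-data generator emulating up-regulated target genes,
    single-cell dropout and amplification depth bias so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'calibration.R'
    'coverage.R'
    'methods.R'
    'pathway-model.R'
    'synthetic.R'
    'variant-panel.R'
    'pipeline.R'
    'wntscreen-package.R'
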