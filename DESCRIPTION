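Package: nrfscope
Title: Consensus Target Gene Sets and Tissue Co-Expression Coherence for
    NRF Transcription Factors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for defining the functional target genes of the
    Cap'n'collar transcription factors NRF1, NRF2 and NRF3 from
    overexpression profiling experiments. Implements per-gene Welch
    (unequal-variance) differential-expression testing on RPKM-like
    abundance matrices, cross-study consensus gene-set construction with
    fold-change concordance regression, RNA-protein concordance against a
    quantitative proteome, a running-sum gene-set enrichment engine with a
    gene-label permutation null, hypergeometric over-representation
    analysis, and multi-tissue co-expression coherence clustering of
    target-gene correlation profiles. A seeded synthetic-data generator
    with planted ground truth (differential effects, cross-study overlap,
    proteome attenuation, tissue correlation modules) lets the whole
    pipeline run and be validated without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    knitr
biocViews: GeneExpression, DifferentialExpression, GeneSetEnrichment,
    Transcriptomics, Proteomics, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
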