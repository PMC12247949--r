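Package: HippoConnect
Title: Hippo-Pathway Transcriptomics and Regulatory-Network Connector Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated, fully testable implementation of a
    cell-type-resolved Hippo-pathway analysis workflow for the developing
    Drosophila ovary: negative-binomial differential expression with
    Benjamini-Hochberg control, PCA with factor-wise variance attribution,
    differential-expression concordance (Venn) classification between hpo and
    yki knockdowns, hypergeometric gene-set over-representation, ChIP-seq
    peak-to-promoter target assignment with multi-dataset intersection, and
    heterogeneous (TF-gene + protein-protein) regulatory-network construction
    with shortest-path connector enumeration. A synthetic-data generator with
    planted ground truth (cell-type, stage and knockdown effects, an outlier
    control sample, promoter-enriched peak sets, and a planted
    hpo-chinmo-yki network motif) makes every stage exercisable and
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'HippoConnect-package.R'
    'utils.R'
    'de_engine.R'
    'enrichment.R'
    'formats_io.R'
    'peak_annotation.R'
    'transcriptomics.R'
    'pipeline.R'
    'regnet.R'
    'synthgen.R'
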