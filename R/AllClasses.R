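#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
NULL

#' Differential expression result table
#'
#' A per-gene result table from [waldDE()], extending
#' \linkS4class{DFrame} in the style of `DESeq2::DESeqResults`. Columns are
#' `baseMean`, `log2FC`, `SE`, `stat`, `pvalue`, `padj` and `significant`;
#' row names are gene identifiers. The contrast and the significance level
#' used for the call live in `metadata()` under `contrast` and `alpha`.
#'
#' @section Validity:
#' All seven columns must be present; `padj` must lie in \[0, 1\] and be
#' no smaller than `pvalue` wherever both are non-missing; `significant`
#' must equal `padj < alpha` (with `NA` padj never significant).
#'
#' @aliases DEResult-class
#' @exportClass DEResult
setClass("DEResult", contains = "DFrame")

setValidity("DEResult", function(object) {
    need <- c("baseMean", "log2FC", "SE", "stat", "pvalue", "padj",
              "significant")
    miss <- setdiff(need, colnames(object))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    padj <- object$padj
    p <- object$pvalue
    ok <- !is.na(padj)
    if (any(padj[ok] < 0 | padj[ok] > 1))
        return("padj outside [0, 1]")
    both <- ok & !is.na(p)
    if (any(padj[both] < p[both] - 1e-12))
        return("padj smaller than pvalue")
    alpha <- metadata(object)$alpha
    if (!is.null(alpha)) {
        want <- !is.na(padj) & padj < alpha
        if (!identical(as.logical(object$significant), as.logical(want)))
            return("significant flag inconsistent with padj < alpha")
    }
    TRUE
})

#' Concordance partition of two differential-expression results
#'
#' Result of [classifyDEOverlap()]: the union of the two significant gene
#' sets partitioned into five disjoint classes — genes significant in both
#' results with the same sign (`sharedUp`, `sharedDown`), significant in
#' both with discordant signs (`opposite`), and significant in exactly one
#' (`exclusiveA`, `exclusiveB`).
#'
#' @slot sharedUp,sharedDown,opposite,exclusiveA,exclusiveB character
#'   vectors of gene identifiers.
#' @slot labels character(2), display labels for the two contrasts.
#'
#' @aliases OverlapPartition-class
#' @exportClass OverlapPartition
setClass("OverlapPartition",
    representation(sharedUp = "character", sharedDown = "character",
                   opposite = "character", exclusiveA = "character",
                   exclusiveB = "character", labels = "character"))

setValidity("OverlapPartition", function(object) {
    sets <- list(object@sharedUp, object@sharedDown, object@opposite,
                 object@exclusiveA, object@exclusiveB)
    all_genes <- unlist(sets)
    if (anyDuplicated(all_genes))
        return("partition classes are not pairwise disjoint")
    TRUE
})

#' Heterogeneous regulatory network
#'
#' A typed edge set over gene/protein identifiers: directed transcription
#' factor to gene edges (`type = "tfgene"`) and undirected protein-protein
#' interaction edges (`type = "ppi"`). PPI edges are stored once, in
#' canonical (lexicographically sorted) endpoint order, and are expanded to
#' two directed arcs at traversal time. Each edge carries a `provenance`
#' attribute recording its source collection.
#'
#' @slot edges a `DataFrame` with columns `source`, `target`, `type`,
#'   `provenance`.
#' @slot nodes character vector, the union of edge endpoints.
#'
#' @aliases RegulatoryNetwork-class
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork",
    representation(edges = "DataFrame", nodes = "character"))

setValidity("RegulatoryNetwork", function(object) {
    ed <- object@edges
    need <- c("source", "target", "type", "provenance")
    if (!all(need %in% colnames(ed)))
        return(paste("edges must have columns", paste(need, collapse = ", ")))
    if (nrow(ed)) {
        if (!all(ed$type %in% c("tfgene", "ppi")))
            return("edge type must be 'tfgene' or 'ppi'")
        ppi <- ed$type == "ppi"
        if (any(ed$source[ppi] > ed$target[ppi]))
            return("ppi edges must be stored in canonical endpoint order")
        if (anyDuplicated(paste(ed$source, ed$target, ed$type, sep = "\r")))
            return("duplicate (source, target, type) edge")
        endpoints <- unique(c(ed$source, ed$target))
        if (!setequal(endpoints, object@nodes))
            return("node set must equal the union of edge endpoints")
    }
    TRUE
})

#' Pipeline configuration
#'
#' Holds every analysis threshold in one validated object: the
#' differential-expression significance level, the promoter flank width,
#' the gene-set filters for GO-style and KEGG-style over-representation,
#' the MAD multiplier for outlier-control flagging, and the global seed.
#'
#' @slot deAlpha BH-adjusted p-value cutoff for differential expression
#'   (default 0.05).
#' @slot promoterFlank promoter half-width around the TSS in bp
#'   (default 1500).
#' @slot goMinSetSize minimum genes per term retained in
#'   over-representation (default 30).
#' @slot goPadjCutoff adjusted-p cutoff for GO-style collections
#'   (default 0.01).
#' @slot keggPadjCutoff adjusted-p cutoff for KEGG-style collections
#'   (default 0.05).
#' @slot outlierMadK MAD multiplier for outlier flagging (default 3).
#' @slot seed integer seed fanned out to all pipeline stages.
#'
#' @aliases PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(deAlpha = "numeric", promoterFlank = "numeric",
                   goMinSetSize = "numeric", goPadjCutoff = "numeric",
                   keggPadjCutoff = "numeric", outlierMadK = "numeric",
                   seed = "numeric"),
    prototype(deAlpha = 0.05, promoterFlank = 1500, goMinSetSize = 30,
              goPadjCutoff = 0.01, keggPadjCutoff = 0.05, outlierMadK = 3,
              seed = 1L))

setValidity("PipelineConfig", function(object) {
    probs <- c(deAlpha = object@deAlpha, goPadjCutoff = object@goPadjCutoff,
               keggPadjCutoff = object@keggPadjCutoff)
    if (any(probs <= 0 | probs > 1))
        return("probability thresholds must lie in (0, 1]")
    if (object@promoterFlank <= 0)
        return("promoterFlank must be > 0")
    if (object@goMinSetSize < 1)
        return("goMinSetSize must be >= 1")
    if (object@outlierMadK <= 0)
        return("outlierMadK must be > 0")
    TRUE
})

#' Synthetic study design
#'
#' Describes the library layout the count simulator realises: factor levels
#' (`cell_type` in germ/soma, `stage` in early/mid/late, `genotype` in
#' control/hpo_RNAi/yki_RNAi), a replicate count per condition, the number
#' of genes and the expected library size. The default design yields the
#' 48-library layout of the emulated study: 27 soma libraries (3 stages x
#' 3 genotypes x 3 replicates), 9 germ controls (3 stages x 3) and 12 germ
#' knockdowns at mid/late only (2 stages x 2 genotypes x 3).
#'
#' @slot replicates data.frame with columns `cell_type`, `stage`,
#'   `genotype`, `n` (replicates per condition, >= 0).
#' @slot nGenes number of simulated genes.
#' @slot librarySize expected total counts per library.
#'
#' @aliases DesignSpec-class
#' @exportClass DesignSpec
setClass("DesignSpec",
    representation(replicates = "data.frame", nGenes = "numeric",
                   librarySize = "numeric"))

setValidity("DesignSpec", function(object) {
    rep <- object@replicates
    need <- c("cell_type", "stage", "genotype", "n")
    if (!all(need %in% colnames(rep)))
        return(paste("replicates needs columns", paste(need, collapse = ", ")))
    if (any(rep$n < 0) || any(rep$n != round(rep$n)))
        return("replicate counts must be non-negative integers")
    if (!all(rep$cell_type %in% c("germ", "soma")))
        return("cell_type levels must be germ/soma")
    if (!all(rep$stage %in% c("early", "mid", "late")))
        return("stage levels must be early/mid/late")
    if (!all(rep$genotype %in% c("control", "hpo_RNAi", "yki_RNAi")))
        return("genotype levels must be control/hpo_RNAi/yki_RNAi")
    if (object@nGenes < 1)
        return("nGenes must be >= 1")
    if (object@librarySize <= 0)
        return("librarySize must be positive")
    TRUE
})
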