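#' @include AllClasses.R
NULL

#' Accessors for HippoConnect classes
#'
#' `networkEdges()` and `networkNodes()` return the edge table and node set
#' of a \linkS4class{RegulatoryNetwork}; `partitionSets()` returns the five
#' disjoint gene sets of an \linkS4class{OverlapPartition} as a named list
#' and `partitionCounts()` their sizes.
#'
#' @param x a `RegulatoryNetwork` or `OverlapPartition`.
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("partitionSets", function(x) standardGeneric("partitionSets"))

#' @rdname accessors
#' @export
setGeneric("partitionCounts", function(x) standardGeneric("partitionCounts"))

#' @rdname accessors
setMethod("networkEdges", "RegulatoryNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("networkNodes", "RegulatoryNetwork", function(x) x@nodes)

#' @rdname accessors
setMethod("partitionSets", "OverlapPartition", function(x)
    list(sharedUp = x@sharedUp, sharedDown = x@sharedDown,
         opposite = x@opposite, exclusiveA = x@exclusiveA,
         exclusiveB = x@exclusiveB))

#' @rdname accessors
setMethod("partitionCounts", "OverlapPartition", function(x)
    vapply(partitionSets(x), length, integer(1)))

setMethod("show", "OverlapPartition", function(object) {
    n <- partitionCounts(object)
    lab <- if (length(object@labels) == 2) object@labels else c("A", "B")
    cat("OverlapPartition (", lab[1], " vs ", lab[2], ")\n", sep = "")
    cat(sprintf("  shared up/down: %d / %d  opposite: %d\n",
                n[["sharedUp"]], n[["sharedDown"]], n[["opposite"]]))
    cat(sprintf("  exclusive to %s: %d  exclusive to %s: %d\n",
                lab[1], n[["exclusiveA"]], lab[2], n[["exclusiveB"]]))
})

setMethod("show", "RegulatoryNetwork", function(object) {
    ed <- object@edges
    cat("RegulatoryNetwork with", length(object@nodes), "nodes and",
        nrow(ed), "edges\n")
    if (nrow(ed)) {
        tab <- table(ed$type)
        cat("  by type:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "\n")
    }
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    cat("  deAlpha:", object@deAlpha,
        " promoterFlank:", object@promoterFlank, "bp\n")
    cat("  goMinSetSize:", object@goMinSetSize,
        " goPadjCutoff:", object@goPadjCutoff,
        " keggPadjCutoff:", object@keggPadjCutoff, "\n")
    cat("  outlierMadK:", object@outlierMadK, " seed:", object@seed, "\n")
})

setMethod("show", "DesignSpec", function(object) {
    cat("DesignSpec:", sum(object@replicates$n), "libraries,",
        object@nGenes, "genes, expected library size",
        object@librarySize, "\n")
})
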