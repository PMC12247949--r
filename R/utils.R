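#' @importFrom GenomicRanges GRanges start end strand seqnames granges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- seqnames<-
NULL

# round half away from zero at `digits` decimals; base round() is banker's
roundHalfUp <- function(x, digits = 0) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}

# TSS coordinate (1-based) per gene: start on '+', end on '-'
tssPositions <- function(genes) {
    str <- as.character(strand(genes))
    if (any(str == "*"))
        stop("unstranded genes are not allowed; strand must be '+' or '-'")
    ifelse(str == "+", start(genes), end(genes))
}

# derive a child seed from a parent seed and a stage offset (kept < 2^31)
childSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}

assertCountMatrix <- function(counts) {
    if (!is.matrix(counts))
        stop("counts must be a matrix")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene row names and sample column names")
    if (anyDuplicated(rownames(counts)))
        stop("duplicate gene IDs in counts")
    if (anyDuplicated(colnames(counts)))
        stop("duplicate sample IDs in counts")
    if (any(is.na(counts)) || any(counts < 0))
        stop("counts must be non-negative")
    if (any(counts != round(counts)))
        stop("counts must be integral")
    invisible(counts)
}

# counts + metadata in either SummarizedExperiment or (matrix, data.frame)
# form; returns list(counts, meta)
splitCountsInput <- function(counts, metadata = NULL) {
    if (methods::is(counts, "SummarizedExperiment")) {
        meta <- as.data.frame(SummarizedExperiment::colData(counts))
        counts <- SummarizedExperiment::assay(counts, "counts")
    } else {
        meta <- as.data.frame(metadata)
    }
    assertCountMatrix(counts)
    if (nrow(meta) && !identical(rownames(meta), colnames(counts))) {
        if (nrow(meta) != ncol(counts))
            stop("metadata rows must match count columns")
        rownames(meta) <- colnames(counts)
    }
    list(counts = counts, meta = meta)
}
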