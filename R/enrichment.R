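#' @include utils.R
NULL

#' Hypergeometric gene-set over-representation
#'
#' Tests a query gene set against each set of a flat collection using the
#' one-sided hypergeometric tail: with population `N = |universe|`,
#' `K = |set within universe|`, `n = |query within universe|` and overlap
#' `k`, `p = P(X >= k)`. Sets smaller than `minSetSize` within the
#' universe are dropped before testing (and before BH adjustment, so the
#' family is the retained sets only). Query genes outside the universe are
#' dropped with a message. Rows with `padj < padjCutoff` are flagged
#' enriched; the table is sorted by `padj`, then `p`, then set name.
#'
#' Default filters follow the workflow's GO-style analysis (minimum 30
#' genes per term, adjusted-p cutoff 0.01); for a KEGG-style analysis use
#' `padjCutoff = 0.05`.
#'
#' @param query character vector of gene IDs.
#' @param sets named list of character vectors (the collection), or a
#'   two-column data.frame `(term_id, gene_id)` as read from a gene-set
#'   TSV.
#' @param universe character vector of all eligible gene IDs.
#' @param minSetSize minimum set size within the universe (default 30).
#' @param padjCutoff BH-adjusted significance cutoff (default 0.01).
#' @return data.frame with columns `set`, `setSize`, `overlap`,
#'   `querySize`, `universeSize`, `pvalue`, `padj`, `enriched`.
#' @examples
#' uni <- paste0("g", 1:100)
#' sets <- list(a = uni[1:40], b = uni[31:90])
#' hypergeomEnrich(uni[1:30], sets, uni, minSetSize = 10,
#'                 padjCutoff = 0.05)
#' @export
hypergeomEnrich <- function(query, sets, universe, minSetSize = 30,
                            padjCutoff = 0.01) {
    if (!length(universe))
        stop("empty universe")
    universe <- unique(universe)
    if (is.data.frame(sets))
        sets <- split(as.character(sets[[2]]), as.character(sets[[1]]))
    if (anyDuplicated(names(sets)))
        stop("set names must be unique")
    query <- unique(query)
    if (!length(query))
        stop("empty query")
    dropped <- sum(!query %in% universe)
    if (dropped)
        message(dropped, " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (!length(query))
        stop("no query genes remain within the universe")

    sets <- lapply(sets, function(s) intersect(unique(s), universe))
    keep <- vapply(sets, length, integer(1)) >= minSetSize
    sets <- sets[keep]
    N <- length(universe); n <- length(query)
    if (!length(sets)) {
        return(data.frame(set = character(), setSize = integer(),
                          overlap = integer(), querySize = integer(),
                          universeSize = integer(), pvalue = numeric(),
                          padj = numeric(), enriched = logical()))
    }
    K <- vapply(sets, length, integer(1))
    k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    padj <- bhAdjust(p)
    out <- data.frame(set = names(sets), setSize = K, overlap = k,
                      querySize = n, universeSize = N, pvalue = p,
                      padj = padj, enriched = padj < padjCutoff,
                      row.names = NULL)
    out[order(out$padj, out$pvalue, out$set), , drop = FALSE]
}
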