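#' @include utils.R
#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# promoter windows around each gene's TSS (1-based closed)
promoterWindows <- function(genes, flank, mode = c("symmetric", "upstream")) {
    mode <- match.arg(mode)
    t <- tssPositions(genes)
    str <- as.character(strand(genes))
    if (mode == "symmetric") {
        st <- t - flank; en <- t + flank
    } else {
        st <- ifelse(str == "+", t - flank, t)
        en <- ifelse(str == "+", t, t + flank)
    }
    GRanges(seqnames(genes), IRanges(pmax(st, 1), en),
            strand = str, gene_id = names(genes))
}

#' Assign ChIP peaks to gene promoters
#'
#' A peak is "in promoter" when its interval overlaps (by at least one
#' base) the promoter window of any gene, defined by default as the
#' symmetric window TSS +/- `flank` (3,001 bases at the default 1,500 bp
#' flank, including the TSS base). Peaks overlapping several windows are
#' assigned to the overlapped gene whose TSS is nearest the peak midpoint
#' (ties to the lexicographically smallest gene ID). With
#' `fallbackNearest = TRUE`, peaks outside every window are additionally
#' mapped to their nearest TSS via [nearestGene()] (they still do not
#' count as in-promoter).
#'
#' @param peaks `GRanges` of peak intervals, named by peak ID.
#' @param genes `GRanges` of gene models named by gene ID, stranded.
#' @param flank promoter half-width in bp (default 1500).
#' @param flankMode `"symmetric"` (TSS +/- flank, default) or
#'   `"upstream"` (flank on the upstream side only).
#' @param fallbackNearest also assign non-promoter peaks to the nearest
#'   TSS (default FALSE).
#' @return list with `assignments` (data.frame: peak, inPromoter, gene,
#'   distance), `fraction` (share of peaks in promoters; `NA` for an
#'   empty peak set, flagged by `empty = TRUE`), `targetGenes` (genes
#'   with >= 1 assigned promoter peak) and `empty`.
#' @examples
#' genes <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(10001, 18001), c(12000, 20000)),
#'     strand = c("+", "-"))
#' names(genes) <- c("gA", "gB")
#' peaks <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(8401, 11601, 15001), c(8600, 11700, 15100)))
#' names(peaks) <- paste0("p", 1:3)
#' assignPromoter(peaks, genes)$fraction
#' @export
assignPromoter <- function(peaks, genes, flank = 1500,
                           flankMode = c("symmetric", "upstream"),
                           fallbackNearest = FALSE) {
    flankMode <- match.arg(flankMode)
    if (flank <= 0)
        stop("flank must be > 0")
    if (length(peaks) == 0) {
        return(list(assignments = data.frame(peak = character(),
                                             inPromoter = logical(),
                                             gene = character(),
                                             distance = numeric()),
                    fraction = NA_real_, targetGenes = character(),
                    empty = TRUE))
    }
    unknown <- setdiff(as.character(unique(seqnames(peaks))),
                       as.character(unique(seqnames(genes))))
    if (length(unknown))
        stop("peaks on chromosomes absent from the annotation: ",
             paste(unknown, collapse = ", "))
    if (is.null(names(peaks)))
        names(peaks) <- paste0("peak_", seq_along(peaks))

    win <- promoterWindows(genes, flank, flankMode)
    hits <- findOverlaps(peaks, win, ignore.strand = TRUE)
    mids <- floor((start(peaks) + end(peaks)) / 2)
    tss <- tssPositions(genes)

    gene <- rep(NA_character_, length(peaks))
    dist <- rep(NA_real_, length(peaks))
    if (length(hits)) {
        qh <- queryHits(hits); sh <- subjectHits(hits)
        d <- abs(mids[qh] - tss[sh])
        ord <- order(qh, d, names(genes)[sh])
        first <- !duplicated(qh[ord])
        sel <- ord[first]
        gene[qh[sel]] <- names(genes)[sh[sel]]
        dist[qh[sel]] <- mids[qh[sel]] - tss[sh[sel]]
    }
    inPromoter <- !is.na(gene)
    targetGenes <- sort(unique(gene[inPromoter]))

    if (fallbackNearest && any(!inPromoter)) {
        ng <- nearestGene(peaks[!inPromoter], genes)
        gene[!inPromoter] <- ng$gene
        dist[!inPromoter] <- ng$distance
    }
    list(assignments = data.frame(peak = names(peaks),
                                  inPromoter = inPromoter,
                                  gene = gene, distance = dist,
                                  row.names = NULL),
         fraction = mean(inPromoter),
         targetGenes = targetGenes,
         empty = FALSE)
}

#' Map each peak to its nearest gene TSS
#'
#' Distance is `|peak midpoint - TSS|`, minimised over genes on the same
#' chromosome; ties go to the lexicographically smallest gene ID, so the
#' mapping is deterministic. Peaks on chromosomes without genes get no
#' assignment (a message reports how many).
#'
#' @param peaks `GRanges` of peaks, named.
#' @param genes `GRanges` of gene models named by gene ID, stranded.
#' @return data.frame with `peak`, `gene` (NA when unassignable) and the
#'   signed `distance` (midpoint minus TSS).
#' @export
nearestGene <- function(peaks, genes) {
    if (is.null(names(peaks)))
        names(peaks) <- paste0("peak_", seq_along(peaks))
    mids <- floor((start(peaks) + end(peaks)) / 2)
    tss <- tssPositions(genes)
    ordG <- order(names(genes))
    gene <- rep(NA_character_, length(peaks))
    dist <- rep(NA_real_, length(peaks))
    pchr <- as.character(seqnames(peaks))
    gchr <- as.character(seqnames(genes))[ordG]
    gid <- names(genes)[ordG]
    gtss <- tss[ordG]
    for (ch in unique(pchr)) {
        gi <- which(gchr == ch)
        pi <- which(pchr == ch)
        if (!length(gi)) next
        for (p in pi) {
            d <- abs(mids[p] - gtss[gi])
            j <- gi[which.min(d)]   # genes sorted by ID: ties -> smallest
            gene[p] <- gid[j]
            dist[p] <- mids[p] - gtss[j]
        }
    }
    nMissing <- sum(is.na(gene))
    if (nMissing)
        message(nMissing, " peak(s) on gene-free chromosomes left ",
                "unassigned")
    data.frame(peak = names(peaks), gene = gene, distance = dist,
               row.names = NULL)
}

#' Multiplicity statistics for several target gene sets
#'
#' Counts, over the union of the supplied sets, the genes appearing in
#' exactly one set (`unique`), in all sets (`commonAll`) and in at least
#' two (`commonAtLeast2`). For any input,
#' `unique + commonAtLeast2 == |union|`.
#'
#' @param sets non-empty list of character vectors of gene IDs.
#' @return list with `perSet` (named sizes), `counts` (named integer
#'   vector: unique, commonAll, commonAtLeast2, union) and `genes` (the
#'   corresponding gene sets).
#' @examples
#' targetSetsIntersection(list(s1 = c("A", "B", "C"),
#'                             s2 = c("B", "C", "D"), s3 = "C"))$counts
#' @export
targetSetsIntersection <- function(sets) {
    if (!length(sets))
        stop("need >= 1 gene set")
    sets <- lapply(sets, unique)
    if (is.null(names(sets)))
        names(sets) <- paste0("set", seq_along(sets))
    mult <- table(unlist(sets))
    uni <- names(mult)[mult == 1]
    all3 <- names(mult)[mult == length(sets)]
    ge2 <- names(mult)[mult >= 2]
    list(perSet = vapply(sets, length, integer(1)),
         counts = c(unique = length(uni), commonAll = length(all3),
                    commonAtLeast2 = length(ge2), union = length(mult)),
         genes = list(unique = sort(uni), commonAll = sort(all3),
                      commonAtLeast2 = sort(ge2)))
}
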