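#' @include AllClasses.R utils.R
NULL

#' PCA of transformed expression values
#'
#' Principal components of the samples on per-gene-centred (unscaled)
#' transformed expression, the standard expression-PCA convention. Signs
#' are made reproducible by forcing the largest-magnitude loading of each
#' component to be positive. Variance fractions are reported over all
#' components and sum to 1.
#'
#' @param x genes x samples numeric matrix (e.g. from [vstTransform()]).
#' @param nComponents number of components to keep in scores/loadings;
#'   default all.
#' @return list with `scores` (samples x PC), `loadings` (genes x PC),
#'   `varFraction` (over all PCs, non-increasing), and `geneMeans`.
#' @examples
#' m <- matrix(rnorm(40), 8, 5,
#'             dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
#' p <- pcaExpression(m)
#' sum(p$varFraction)
#' @export
pcaExpression <- function(x, nComponents = NULL) {
    if (ncol(x) < 2)
        stop("PCA needs >= 2 samples")
    mu <- rowMeans(x)
    cx <- x - mu
    if (all(abs(cx) < 1e-12))
        stop("matrix has zero variance; PCA undefined")
    pc <- stats::prcomp(t(cx), center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2
    varFraction <- ev / sum(ev)
    for (k in seq_len(ncol(pc$rotation))) {
        j <- which.max(abs(pc$rotation[, k]))
        if (pc$rotation[j, k] < 0) {
            pc$rotation[, k] <- -pc$rotation[, k]
            pc$x[, k] <- -pc$x[, k]
        }
    }
    keep <- if (is.null(nComponents)) ncol(pc$x)
            else min(nComponents, ncol(pc$x))
    list(scores = pc$x[, seq_len(keep), drop = FALSE],
         loadings = pc$rotation[, seq_len(keep), drop = FALSE],
         varFraction = varFraction,
         geneMeans = mu)
}

#' Variance of PC scores attributable to a sample factor
#'
#' For each principal component, the coefficient of determination of a
#' one-way decomposition of the scores by the factor:
#' `R^2 = SS_between / SS_total`, in \[0, 1\]. A factor that perfectly
#' splits a component's scores gives 1; unrelated labels give values
#' near 0.
#'
#' @param scores samples x PC score matrix from [pcaExpression()].
#' @param metadata per-sample data.frame.
#' @param factor name of the metadata column to attribute.
#' @return named numeric vector, one R-squared per component.
#' @export
factorVarianceAttribution <- function(scores, metadata, factor) {
    if (!factor %in% colnames(metadata))
        stop("factor '", factor, "' not in metadata")
    f <- as.factor(metadata[[factor]])
    if (length(f) != nrow(scores))
        stop("metadata rows must match score rows")
    apply(scores, 2, function(s) {
        tot <- sum((s - mean(s))^2)
        if (tot < 1e-300) return(0)
        gm <- tapply(s, f, mean)
        ns <- tapply(s, f, length)
        sum(ns * (gm - mean(s))^2) / tot
    })
}

#' Classify the concordance of two differential-expression results
#'
#' Partitions the union of the two significant gene sets into the five
#' disjoint classes of an \linkS4class{OverlapPartition}: shared
#' same-direction (up or down), opposite-direction (significant in both,
#' discordant log2FC signs), and exclusive to either contrast.
#'
#' @param deA,deB \linkS4class{DEResult} objects over the same gene
#'   universe.
#' @param alpha optional significance level; when omitted each result's
#'   stored `significant` call is used.
#' @param labels character(2) display labels for the two contrasts.
#' @return an \linkS4class{OverlapPartition}.
#' @examples
#' sim <- makeCounts(designSpec(nGenes = 60), seed = 3)
#' germ <- sim[, sim$cell_type == "germ" & sim$stage != "early"]
#' a <- waldDE(germ, contrast = c("genotype", "hpo_RNAi", "control"))
#' b <- waldDE(germ, contrast = c("genotype", "yki_RNAi", "control"))
#' classifyDEOverlap(a, b, labels = c("hpo", "yki"))
#' @export
classifyDEOverlap <- function(deA, deB, alpha = NULL,
                              labels = c("A", "B")) {
    gA <- rownames(deA); gB <- rownames(deB)
    if (!setequal(gA, gB)) {
        d <- length(union(setdiff(gA, gB), setdiff(gB, gA)))
        stop("gene universes differ (symmetric difference: ", d, " genes)")
    }
    deB <- deB[gA, ]
    sig <- function(de) {
        if (is.null(alpha)) as.logical(de$significant)
        else !is.na(de$padj) & de$padj < alpha
    }
    sA <- sig(deA); sB <- sig(deB)
    both <- sA & sB
    sgnA <- sign(deA$log2FC); sgnB <- sign(deB$log2FC)
    concord <- both & sgnA == sgnB
    methods::new("OverlapPartition",
        sharedUp = gA[concord & sgnA > 0],
        sharedDown = gA[concord & sgnA < 0],
        opposite = gA[both & sgnA != sgnB],
        exclusiveA = gA[sA & !sB],
        exclusiveB = gA[sB & !sA],
        labels = labels)
}

#' Fraction of differentially expressed genes shared by two contrasts
#'
#' `100 * |shared| / |sigA union sigB|`, where shared genes are those
#' significant in both contrasts (same-direction up + down, and — by
#' default, since they are significant in both — the opposite-direction
#' genes). Reported rounded half-away-from-zero to the nearest integer;
#' the raw value is also returned. Invariant to swapping the two
#' contrasts.
#'
#' @param partition an \linkS4class{OverlapPartition}.
#' @param includeOpposite count opposite-direction genes as shared
#'   (default TRUE).
#' @return list with `percent` (integer-rounded) and `raw`.
#' @examples
#' # worked example from printed germ-line marginals: 51% shared
#' p <- overlapPartitionFromCounts(sharedUp = 245, sharedDown = 869,
#'                                 opposite = 1, exclusiveA = 467,
#'                                 exclusiveB = 605)
#' sharedFraction(p)$percent
#' @export
sharedFraction <- function(partition, includeOpposite = TRUE) {
    n <- partitionCounts(partition)
    shared <- n[["sharedUp"]] + n[["sharedDown"]] +
        if (includeOpposite) n[["opposite"]] else 0
    unionSize <- sum(n)
    if (unionSize == 0) {
        warning("no significant genes in either contrast")
        return(list(percent = NA_real_, raw = NA_real_))
    }
    raw <- 100 * shared / unionSize
    list(percent = roundHalfUp(raw, 0), raw = raw)
}

#' Build an OverlapPartition from class counts
#'
#' Convenience constructor for worked examples where only the partition
#' sizes are known (e.g. printed Venn marginals): generates placeholder
#' gene IDs of the requested multiplicities.
#'
#' @param sharedUp,sharedDown,opposite,exclusiveA,exclusiveB class sizes.
#' @param labels character(2) contrast labels.
#' @return an \linkS4class{OverlapPartition}.
#' @export
overlapPartitionFromCounts <- function(sharedUp = 0, sharedDown = 0,
                                       opposite = 0, exclusiveA = 0,
                                       exclusiveB = 0,
                                       labels = c("A", "B")) {
    mk <- function(prefix, n)
        if (n > 0) paste0(prefix, "_", seq_len(n)) else character()
    methods::new("OverlapPartition",
        sharedUp = mk("su", sharedUp), sharedDown = mk("sd", sharedDown),
        opposite = mk("op", opposite), exclusiveA = mk("ea", exclusiveA),
        exclusiveB = mk("eb", exclusiveB), labels = labels)
}

#' Percent excess of upregulated over downregulated genes
#'
#' `100 * (nUp - nDown) / nDown`, reported half-away-from-zero to one
#' decimal (raw value also returned). Undefined when `nDown` is 0.
#'
#' @param nUp,nDown counts of up- and downregulated genes.
#' @return list with `percent` (one decimal) and `raw`.
#' @examples
#' updownExcess(231, 143)$percent  # 61.5
#' updownExcess(365, 310)$percent  # 17.7
#' @export
updownExcess <- function(nUp, nDown) {
    if (nDown == 0)
        stop("updown excess undefined for nDown = 0")
    raw <- 100 * (nUp - nDown) / nDown
    list(percent = roundHalfUp(raw, 1), raw = raw)
}
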