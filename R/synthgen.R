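#' @include AllClasses.R utils.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowData
NULL

#' Construct a synthetic study design
#'
#' The default replicate map reproduces the emulated study's 48-library
#' layout: three replicates for every somatic condition (3 stages x 3
#' genotypes = 27), three for every germ-line control (9), and three for
#' the germ-line knockdowns at mid and late stages only (12). The two
#' single-replicate early-germ knockdown libraries can be added with
#' `includeEarlyGermKD = TRUE`; they are generable but conventionally
#' excluded from differential expression.
#'
#' @param nGenes simulated genes (default 2000).
#' @param librarySize expected total counts per library (default 5e5).
#' @param includeEarlyGermKD add one early-stage germ library per
#'   knockdown genotype (default FALSE).
#' @param replicates optional custom replicate map (data.frame with
#'   `cell_type`, `stage`, `genotype`, `n`), overriding the default.
#' @return a \linkS4class{DesignSpec}.
#' @examples
#' sum(designReplicates(designSpec())$n)  # 48
#' @export
designSpec <- function(nGenes = 2000, librarySize = 5e5,
                       includeEarlyGermKD = FALSE, replicates = NULL) {
    if (is.null(replicates)) {
        soma <- expand.grid(cell_type = "soma",
                            stage = c("early", "mid", "late"),
                            genotype = c("control", "hpo_RNAi", "yki_RNAi"),
                            stringsAsFactors = FALSE)
        soma$n <- 3L
        germC <- data.frame(cell_type = "germ",
                            stage = c("early", "mid", "late"),
                            genotype = "control", n = 3L)
        germKD <- expand.grid(cell_type = "germ",
                              stage = c("mid", "late"),
                              genotype = c("hpo_RNAi", "yki_RNAi"),
                              stringsAsFactors = FALSE)
        germKD$n <- 3L
        replicates <- rbind(soma, germC, germKD)
        if (includeEarlyGermKD)
            replicates <- rbind(replicates,
                data.frame(cell_type = "germ", stage = "early",
                           genotype = c("hpo_RNAi", "yki_RNAi"), n = 1L))
    }
    methods::new("DesignSpec", replicates = replicates, nGenes = nGenes,
                 librarySize = librarySize)
}

#' @rdname designSpec
#' @param design a `DesignSpec`.
#' @export
designReplicates <- function(design) design@replicates

#' Generate a synthetic gene annotation
#'
#' Non-overlapping gene models placed sequentially along `nChroms`
#' chromosomes with random widths (200-2000 bp), random gaps (500-2000
#' bp) and random strands; the TSS is the start on `+` and the end on
#' `-`. Deterministic under a fixed seed. When the requested genes cannot
#' fit on the given chromosome length, an explicit capacity error is
#' raised; by default the chromosome length is auto-sized to fit.
#'
#' @param nGenes number of genes (>= 1).
#' @param nChroms number of chromosomes (default 3).
#' @param chromLength chromosome length in bp; `NULL` auto-sizes.
#' @param seed integer seed.
#' @return a named, stranded `GRanges` with seqlengths set.
#' @examples
#' makeAnnotation(5, nChroms = 1, seed = 7)
#' @export
makeAnnotation <- function(nGenes, nChroms = 3, chromLength = NULL,
                           seed = 1) {
    if (nGenes < 1)
        stop("nGenes must be >= 1")
    set.seed(seed)
    perChrom <- ceiling(nGenes / nChroms)
    auto <- is.null(chromLength)
    if (auto)
        chromLength <- 10000 + perChrom * 4200
    chromOf <- rep(seq_len(nChroms), length.out = nGenes)
    widths <- sample(200:2000, nGenes, replace = TRUE)
    gaps <- sample(500:2000, nGenes, replace = TRUE)
    strands <- sample(c("+", "-"), nGenes, replace = TRUE)
    chrom <- start <- integer(nGenes)
    for (c in seq_len(nChroms)) {
        idx <- which(chromOf == c)
        if (!length(idx)) next
        # leave headroom at the chromosome start for promoter windows
        st <- 5000 + cumsum(c(0, (widths[idx] + gaps[idx])[-length(idx)]))
        en <- st + widths[idx] - 1
        if (any(en > chromLength - 5000))
            stop("capacity error: ", length(idx), " genes do not fit on a ",
                 "chromosome of length ", chromLength)
        chrom[idx] <- c
        start[idx] <- st
    }
    gr <- GRanges(paste0("chr", chrom),
                  IRanges(start, width = widths), strand = strands)
    names(gr) <- sprintf("gene%04d", seq_len(nGenes))
    mcols(gr)$gene_id <- names(gr)
    seqlengths(gr) <- stats::setNames(rep(chromLength, nChroms),
                                      paste0("chr", seq_len(nChroms)))
    gr
}

#' Generate a planted ground-truth table
#'
#' Assigns each gene a concordance class and true per-contrast log2
#' fold-changes encoding the qualitative structure the simulator emulates:
#' a dominant cell-type effect, a stage effect confined to the soma,
#' germ-line knockdown responses largely shared between the hpo and yki
#' contrasts (with a single opposite-direction gene), soma responses
#' largely exclusive to one knockdown (with four opposite genes), and
#' marker genes `hpo`, `yki`, `chinmo` carrying their own knockdown
#' signatures (including the weak `yki` reduction under hpo knockdown in
#' the germ line). Remaining genes are null with all true fold-changes 0.
#'
#' @param design a \linkS4class{DesignSpec}.
#' @param seed integer seed.
#' @param dispersion NB dispersion given to every gene (default 0.05).
#' @return a data.frame with one row per gene: `gene_id`, `class`,
#'   `baseline`, `dispersion` and the per-contrast true log2FC columns
#'   (`lfc_celltype`, `lfc_stage_mid`, `lfc_stage_late`, `lfc_germ_hpo`,
#'   `lfc_germ_yki`, `lfc_soma_hpo`, `lfc_soma_yki`).
#' @export
makeTruth <- function(design = designSpec(), seed = 1, dispersion = 0.05) {
    set.seed(childSeed(seed, 1))
    n <- design@nGenes
    ids <- sprintf("gene%04d", seq_len(n))
    markers <- c("hpo", "yki", "chinmo")
    nm <- min(3, n)
    ids[seq_len(nm)] <- markers[seq_len(nm)]

    tt <- data.frame(gene_id = ids, class = "null",
                     baseline = stats::rlnorm(n,
                         meanlog = log(design@librarySize / n), sdlog = 1),
                     dispersion = dispersion,
                     lfc_celltype = 0, lfc_stage_mid = 0, lfc_stage_late = 0,
                     lfc_germ_hpo = 0, lfc_germ_yki = 0,
                     lfc_soma_hpo = 0, lfc_soma_yki = 0,
                     stringsAsFactors = FALSE)
    tt$class[seq_len(nm)] <- "marker"
    # marker genes: strong self-knockdown, plus the planted cross-effects
    if (n >= 1) {  # hpo
        tt[1, c("lfc_germ_hpo", "lfc_soma_hpo")] <- -4.1
        tt$baseline[1] <- max(tt$baseline[1], 200)
    }
    if (n >= 2) {  # yki: self-knockdown, weak reduction under hpo RNAi
        tt[2, c("lfc_germ_yki", "lfc_soma_yki")] <- -2
        tt[2, "lfc_germ_hpo"] <- -0.8
        tt$baseline[2] <- max(tt$baseline[2], 200)
    }
    if (n >= 3)    # chinmo: upregulated under yki knockdown in the germ line
        tt[3, "lfc_germ_yki"] <- 1

    pool <- setdiff(seq_len(n), seq_len(nm))
    take <- function(k) {
        k <- min(k, length(pool))
        out <- pool[seq_len(k)]
        pool <<- pool[-seq_len(k)]
        out
    }
    rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)

    ct <- take(round(0.30 * n))
    tt$class[ct] <- "celltype"
    tt$lfc_celltype[ct] <- rsign(length(ct)) * stats::runif(length(ct), 2, 4)

    stg <- take(round(0.10 * n))
    tt$class[stg] <- "stage"
    s <- rsign(length(stg))
    tt$lfc_stage_mid[stg] <- s * stats::runif(length(stg), 0.8, 1.6)
    tt$lfc_stage_late[stg] <- s * stats::runif(length(stg), 1.4, 2.4)

    gs <- take(round(0.12 * n))
    tt$class[gs] <- "germ_shared"
    sgn <- ifelse(stats::runif(length(gs)) < 0.7, -1, 1)
    lfc <- sgn * stats::runif(length(gs), 1.5, 3)
    tt$lfc_germ_hpo[gs] <- lfc
    tt$lfc_germ_yki[gs] <- sgn * stats::runif(length(gs), 1.5, 3)

    geh <- take(round(0.02 * n))
    tt$class[geh] <- "germ_exclusive_hpo"
    tt$lfc_germ_hpo[geh] <- rsign(length(geh)) *
        stats::runif(length(geh), 1.5, 3)
    gey <- take(round(0.02 * n))
    tt$class[gey] <- "germ_exclusive_yki"
    tt$lfc_germ_yki[gey] <- rsign(length(gey)) *
        stats::runif(length(gey), 1.5, 3)

    gop <- take(1)
    if (length(gop)) {  # down under hpo RNAi, up under yki RNAi
        tt$class[gop] <- "germ_opposite"
        tt$lfc_germ_hpo[gop] <- -2.5
        tt$lfc_germ_yki[gop] <- 2.5
    }

    ss <- take(round(0.005 * n))
    tt$class[ss] <- "soma_shared"
    sgn <- rsign(length(ss))
    tt$lfc_soma_hpo[ss] <- sgn * stats::runif(length(ss), 1.5, 3)
    tt$lfc_soma_yki[ss] <- sgn * stats::runif(length(ss), 1.5, 3)

    seh <- take(round(0.03 * n))
    tt$class[seh] <- "soma_exclusive_hpo"
    tt$lfc_soma_hpo[seh] <- rsign(length(seh)) *
        stats::runif(length(seh), 1.5, 3)
    sey <- take(round(0.015 * n))
    tt$class[sey] <- "soma_exclusive_yki"
    tt$lfc_soma_yki[sey] <- rsign(length(sey)) *
        stats::runif(length(sey), 1.5, 3)

    sop <- take(4)
    if (length(sop)) {
        tt$class[sop] <- "soma_opposite"
        sgn <- rsign(length(sop))
        tt$lfc_soma_hpo[sop] <- sgn * 2.5
        tt$lfc_soma_yki[sop] <- -sgn * 2.5
    }
    tt
}

#' Simulate a count matrix with planted effects
#'
#' Draws gene x library counts from a negative binomial with
#' `mean = baseline x trueSizeFactor x 2^(sum of planted effects)` and
#' gene-wise dispersion `alpha` (`variance = mu + alpha mu^2`; `alpha = 0`
#' gives Poisson). Effects applied per library: the cell-type fold-change
#' in germ libraries, the stage fold-changes in soma libraries, and the
#' cell-type-specific knockdown fold-change matching the library's
#' genotype. Optionally one designated germ-line mid-stage control library
#' has its marker-gene mean multiplied by `outlierFactor` (default 0.1),
#' planting an anomalously low marker control for outlier-flag testing.
#'
#' @param design a \linkS4class{DesignSpec}; the default yields exactly
#'   48 libraries.
#' @param truth optional truth table from [makeTruth()] (or any
#'   data.frame with its columns; missing effect columns are taken as 0).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param plantOutlier plant the suppressed-marker control (default TRUE).
#' @param outlierFactor multiplicative suppression (default 0.1).
#' @param marker marker gene for the outlier (default `"yki"`).
#' @return a `SummarizedExperiment`: `counts` assay, sample metadata
#'   (`cell_type`, `stage`, `genotype`, `replicate`, `plantedOutlier`) in
#'   `colData`, and the truth table in `rowData`.
#' @examples
#' se <- makeCounts(designSpec(nGenes = 100), seed = 1)
#' dim(se)  # 100 genes x 48 libraries
#' @export
makeCounts <- function(design = designSpec(), truth = NULL, seed = 1,
                       plantOutlier = TRUE, outlierFactor = 0.1,
                       marker = "yki") {
    if (is.null(truth))
        truth <- makeTruth(design, seed = seed)
    truth <- as.data.frame(truth)
    effectCols <- c("lfc_celltype", "lfc_stage_mid", "lfc_stage_late",
                    "lfc_germ_hpo", "lfc_germ_yki", "lfc_soma_hpo",
                    "lfc_soma_yki")
    for (cc in effectCols)
        if (!cc %in% colnames(truth)) truth[[cc]] <- 0
    if (!"dispersion" %in% colnames(truth))
        stop("truth table needs a dispersion column")
    if (any(truth$dispersion < 0))
        stop("dispersion must be >= 0")
    if (!all(is.finite(as.matrix(truth[, effectCols]))))
        stop("planted effects must be finite")

    rep <- design@replicates
    meta <- do.call(rbind, lapply(seq_len(nrow(rep)), function(i) {
        if (rep$n[i] == 0) return(NULL)
        data.frame(cell_type = rep$cell_type[i], stage = rep$stage[i],
                   genotype = rep$genotype[i],
                   replicate = seq_len(rep$n[i]),
                   stringsAsFactors = FALSE)
    }))
    rownames(meta) <- paste(meta$cell_type, meta$stage, meta$genotype,
                            paste0("r", meta$replicate), sep = "_")
    nS <- nrow(meta); nG <- nrow(truth)

    set.seed(childSeed(seed, 2))
    sfTrue <- stats::runif(nS, 0.7, 1.3)

    lfc <- matrix(0, nG, nS)
    germ <- meta$cell_type == "germ"
    lfc[, germ] <- lfc[, germ] + truth$lfc_celltype
    midS <- meta$cell_type == "soma" & meta$stage == "mid"
    lateS <- meta$cell_type == "soma" & meta$stage == "late"
    lfc[, midS] <- lfc[, midS] + truth$lfc_stage_mid
    lfc[, lateS] <- lfc[, lateS] + truth$lfc_stage_late
    for (j in seq_len(nS)) {
        if (meta$genotype[j] == "control") next
        kd <- if (meta$genotype[j] == "hpo_RNAi") "hpo" else "yki"
        col <- paste0("lfc_", meta$cell_type[j], "_", kd)
        lfc[, j] <- lfc[, j] + truth[[col]]
    }
    mu <- truth$baseline * 2^lfc
    mu <- sweep(mu, 2, sfTrue, "*")

    meta$plantedOutlier <- FALSE
    if (plantOutlier && marker %in% truth$gene_id) {
        out <- which(germ & meta$stage == "mid" &
                     meta$genotype == "control")[1]
        if (!is.na(out)) {
            mu[match(marker, truth$gene_id), out] <-
                mu[match(marker, truth$gene_id), out] * outlierFactor
            meta$plantedOutlier[out] <- TRUE
        }
    }

    counts <- matrix(0L, nG, nS,
                     dimnames = list(truth$gene_id, rownames(meta)))
    alpha <- truth$dispersion
    pois <- alpha == 0
    for (j in seq_len(nS)) {
        if (any(pois))
            counts[pois, j] <- stats::rpois(sum(pois), mu[pois, j])
        if (any(!pois))
            counts[!pois, j] <- stats::rnbinom(sum(!pois),
                mu = mu[!pois, j], size = 1 / alpha[!pois])
    }
    meta$trueSizeFactor <- sfTrue
    SummarizedExperiment(assays = list(counts = counts),
                         colData = S4Vectors::DataFrame(meta),
                         rowData = S4Vectors::DataFrame(truth,
                             row.names = truth$gene_id))
}

#' Simulate ChIP peak sets with a controlled promoter fraction
#'
#' Each peak is independently a "promoter peak" with probability
#' `promoterFraction`: placed so that its interval overlaps the symmetric
#' window TSS +/- `flank` of a randomly chosen gene. Non-promoter peaks
#' are placed, by rejection, outside every promoter window; if no such
#' space exists a capacity error is raised. The realised promoter count
#' is therefore Binomial(`nPeaks`, `promoterFraction`), which is what
#' [assignPromoter()] recovers.
#'
#' @param annotation gene `GRanges` from [makeAnnotation()] (needs
#'   seqlengths).
#' @param nPeaks number of peaks (0 gives an empty set).
#' @param promoterFraction probability a peak is placed in a promoter
#'   (default 0.72, the midpoint-ish of the emulated 69-75% range).
#' @param flank promoter half-width (default 1500).
#' @param peakWidth peak width in bp (default 200).
#' @param seed integer seed.
#' @return a named `GRanges` of peaks with a `score` column.
#' @export
makePeaks <- function(annotation, nPeaks, promoterFraction = 0.72,
                      flank = 1500, peakWidth = 200, seed = 1) {
    if (promoterFraction < 0 || promoterFraction > 1)
        stop("promoterFraction must lie in [0, 1]")
    if (flank <= 0)
        stop("flank must be > 0")
    if (nPeaks == 0)
        return(GRanges(seqlengths = seqlengths(annotation)))
    set.seed(childSeed(seed, 3))
    win <- promoterWindows(annotation, flank)
    tss <- tssPositions(annotation)
    chr <- as.character(seqnames(annotation))
    lens <- seqlengths(annotation)
    if (any(is.na(lens)))
        stop("annotation needs seqlengths")

    isProm <- stats::runif(nPeaks) < promoterFraction
    half <- floor(peakWidth / 2)
    outChr <- character(nPeaks); outStart <- integer(nPeaks)

    for (i in seq_len(nPeaks)) {
        if (isProm[i]) {
            placed <- FALSE
            for (try in seq_len(50)) {
                g <- sample(length(annotation), 1)
                mid <- tss[g] + sample(seq(-flank, flank), 1)
                st <- max(1, mid - half)
                en <- min(lens[[chr[g]]], st + peakWidth - 1)
                st <- en - peakWidth + 1
                # verify the clamped interval still overlaps the window
                if (st <= tss[g] + flank && en >= tss[g] - flank) {
                    outChr[i] <- chr[g]; outStart[i] <- st
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop("could not place a promoter peak; widen chromosomes")
        } else {
            placed <- FALSE
            for (try in seq_len(1000)) {
                ch <- sample(names(lens), 1)
                st <- sample(lens[[ch]] - peakWidth + 1, 1)
                cand <- GRanges(ch, IRanges(st, st + peakWidth - 1))
                if (!length(findOverlaps(cand, win,
                                         ignore.strand = TRUE))) {
                    outChr[i] <- ch; outStart[i] <- st
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop("capacity error: no non-promoter space available ",
                     "(promoter windows cover the genome)")
        }
    }
    gr <- GRanges(outChr, IRanges(outStart, width = peakWidth),
                  score = round(stats::runif(nPeaks) * 1000),
                  seqlengths = lens)
    names(gr) <- sprintf("peak%05d", seq_len(nPeaks))
    mcols(gr)$plantedPromoter <- isProm
    gr
}

#' Simulate a regulatory network with a planted connector motif
#'
#' Generates `nTfgeneEdges` random directed TF-to-target edges and
#' `nPpiEdges` random undirected PPI edges over `nTFs` transcription
#' factors and `nGenes` target genes, sampled without replacement so edge
#' counts after deduplication equal the request. With
#' `plantMotif = TRUE`, the nodes `hpo`, `chinmo`, `yki` are added with
#' the motif edges `ppi(hpo, chinmo)`, `tfgene(chinmo -> yki)`,
#' `tfgene(chinmo -> hpo)` and `tfgene(yki -> chinmo)`; random edges are
#' constructed so that no other hpo-to-yki path of length <= 2 can arise
#' (`hpo` and `yki` are not TF sources and random PPI edges avoid `hpo`),
#' and a post-generation validation errors if the guarantee is ever
#' violated.
#'
#' @param nTFs,nGenes node counts for the random part.
#' @param nTfgeneEdges,nPpiEdges random edge counts (the 4 motif edges
#'   are extra).
#' @param plantMotif plant the hpo-chinmo-yki motif (default TRUE).
#' @param seed integer seed.
#' @return list with data.frames `tfgene` and `ppi` (columns `source`,
#'   `target`, `provenance`), ready for [buildNetwork()].
#' @examples
#' nw <- makeNetwork(nTFs = 5, nGenes = 20, nTfgeneEdges = 15,
#'                   nPpiEdges = 10, seed = 1)
#' net <- buildNetwork(tfgene = nw$tfgene, ppi = nw$ppi)
#' enumerateConnectors(net, "hpo", "yki")$connectors
#' @export
makeNetwork <- function(nTFs = 20, nGenes = 150, nTfgeneEdges = 300,
                        nPpiEdges = 200, plantMotif = TRUE, seed = 1) {
    set.seed(childSeed(seed, 4))
    tfs <- if (nTFs > 0) sprintf("tf%03d", seq_len(nTFs)) else character()
    genes <- if (nGenes > 0) sprintf("g%04d", seq_len(nGenes))
             else character()
    motif <- c("hpo", "chinmo", "yki")
    if (plantMotif) {
        tfs <- c(tfs, "chinmo")
        genes <- c(genes, "hpo", "yki")
    }
    nodes <- c(tfs, genes)

    # candidate directed TF->target pairs, excluding self-loops and any
    # pair that could complete an alternative hpo->yki shortcut
    candTf <- expand.grid(source = tfs, target = nodes,
                          stringsAsFactors = FALSE)
    candTf <- candTf[candTf$source != candTf$target, , drop = FALSE]
    if (plantMotif) {
        planted <- paste(c("chinmo", "chinmo", "yki"),
                         c("yki", "hpo", "chinmo"))
        candTf <- candTf[!paste(candTf$source, candTf$target) %in% planted,
                         , drop = FALSE]
    }
    if (nTfgeneEdges > nrow(candTf))
        stop("nTfgeneEdges exceeds the number of available TF->target pairs")
    tfEdges <- candTf[sample(nrow(candTf), nTfgeneEdges), , drop = FALSE]

    # candidate unordered PPI pairs; random PPI edges never touch hpo, so
    # hpo's only neighbour is the planted chinmo interaction
    ppiNodes <- setdiff(nodes, if (plantMotif) "hpo" else character())
    candPpi <- if (length(ppiNodes) >= 2) {
        idx <- utils::combn(sort(ppiNodes), 2)
        data.frame(source = idx[1, ], target = idx[2, ],
                   stringsAsFactors = FALSE)
    } else data.frame(source = character(), target = character())
    if (nPpiEdges > nrow(candPpi))
        stop("nPpiEdges exceeds the number of available PPI pairs")
    ppiEdges <- candPpi[sample(nrow(candPpi), max(nPpiEdges, 0)), ,
                        drop = FALSE]

    if (plantMotif) {
        tfEdges <- rbind(tfEdges,
            data.frame(source = c("chinmo", "chinmo", "yki"),
                       target = c("yki", "hpo", "chinmo")))
        ppiEdges <- rbind(ppiEdges,
            data.frame(source = "chinmo", target = "hpo"))
        validateMotifSafety(tfEdges, ppiEdges)
    }
    tfEdges$provenance <- rep("droid-like", nrow(tfEdges))
    ppiEdges$provenance <- rep("droid-like", nrow(ppiEdges))
    rownames(tfEdges) <- rownames(ppiEdges) <- NULL
    list(tfgene = tfEdges, ppi = ppiEdges)
}

# assert that no hpo->yki path of length <= 2 bypasses chinmo
validateMotifSafety <- function(tfEdges, ppiEdges) {
    usable <- function(a, b)
        any(tfEdges$source == a & tfEdges$target == b) ||
        any((ppiEdges$source == a & ppiEdges$target == b) |
            (ppiEdges$source == b & ppiEdges$target == a))
    if (usable("hpo", "yki"))
        stop("generation error: direct hpo-yki edge present")
    mids <- setdiff(unique(c(tfEdges$source, tfEdges$target,
                             ppiEdges$source, ppiEdges$target)),
                    c("hpo", "yki", "chinmo"))
    for (w in mids)
        if (usable("hpo", w) && usable(w, "yki"))
            stop("generation error: alternative two-step hpo->yki path ",
                 "via ", w)
    invisible(TRUE)
}

#' Generate a gene-set collection with planted enrichment
#'
#' Builds a flat collection over the simulated gene universe: one set per
#' planted truth class that is large enough (padded with random genes up
#' to `setSize` so it passes the minimum-size filter), plus purely random
#' sets. A query of genes from a planted class is then strongly enriched
#' for that class's set and near-uniform on the random sets.
#'
#' @param truth truth table from [makeTruth()] (or the `rowData` of a
#'   simulated experiment).
#' @param setSize target set size (default 60).
#' @param nRandomSets number of random background sets (default 8).
#' @param seed integer seed.
#' @return list with `sets` (named list of gene ID vectors) and
#'   `universe`.
#' @export
makeGeneSets <- function(truth, setSize = 60, nRandomSets = 8, seed = 1) {
    set.seed(childSeed(seed, 5))
    truth <- as.data.frame(truth)
    universe <- truth$gene_id
    sets <- list()
    for (cl in c("germ_shared", "celltype", "soma_exclusive_hpo")) {
        members <- truth$gene_id[truth$class == cl]
        if (!length(members)) next
        if (length(members) < setSize)
            members <- c(members,
                sample(setdiff(universe, members),
                       min(setSize - length(members),
                           length(universe) - length(members))))
        sets[[paste0("planted_", cl)]] <- sample(members, length(members))
    }
    for (i in seq_len(nRandomSets))
        sets[[sprintf("random_%02d", i)]] <-
            sample(universe, min(setSize, length(universe)))
    list(sets = sets, universe = universe)
}
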