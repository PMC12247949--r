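#' @include formats_io.R de_engine.R transcriptomics.R enrichment.R
#'   peak_annotation.R regnet.R synthgen.R
NULL

#' Write and read differential-expression result tables
#'
#' Results travel as TSV with columns `gene_id`, `baseMean`, `log2FC`,
#' `SE`, `stat`, `pvalue`, `padj`, `significant`; the contrast and alpha
#' are kept in a leading `#` header line so a round trip restores the
#' full \linkS4class{DEResult}.
#'
#' @param res a `DEResult`.
#' @param path TSV file.
#' @return `readDEResult()`: a `DEResult`.
#' @export
writeDEResult <- function(res, path) {
    md <- metadata(res)
    header <- sprintf("# contrast=%s alpha=%s",
                      paste(md$contrast, collapse = ":"), md$alpha)
    tab <- data.frame(gene_id = rownames(res), as.data.frame(res),
                      check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeDEResult
#' @export
readDEResult <- function(path) {
    first <- readLines(path, n = 1)
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    df <- S4Vectors::DataFrame(tab[, -1, drop = FALSE],
                               row.names = tab$gene_id)
    out <- methods::new("DEResult", df)
    if (grepl("^# contrast=", first)) {
        contr <- sub("^# contrast=(\\S+) .*", "\\1", first)
        alpha <- as.numeric(sub(".* alpha=", "", first))
        metadata(out) <- list(contrast = strsplit(contr, ":")[[1]],
                              alpha = alpha)
    }
    out
}

# significance tallies for one DE result
deCounts <- function(res) {
    sig <- as.logical(res$significant)
    list(nTested = sum(!is.na(res$pvalue)),
         nSig = sum(sig),
         nUp = sum(sig & res$log2FC > 0),
         nDown = sum(sig & res$log2FC < 0))
}

#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates every stage under one configuration and one seed:
#' simulate counts/annotation/peaks/network, flag and drop the
#' anomalous-marker control, run the four knockdown-vs-control contrasts
#' (germ and soma, hpo and yki; germ contrasts on mid+late stages),
#' PCA with cell-type variance attribution, concordance classification of
#' the two contrast pairs with shared-fraction and up/down-excess
#' statistics, over-representation of the shared germ-line downregulated
#' genes, promoter assignment and intersection of three peak datasets,
#' and regulatory-network connector enumeration between `hpo` and `yki`.
#' Identical seeds give identical output bundles.
#'
#' @param config a \linkS4class{PipelineConfig}; `config@seed` drives
#'   every stage through fixed per-stage child seeds.
#' @param outDir output directory (created); stage TSVs plus
#'   `summary.json` are written there. `NULL` skips writing.
#' @param design a \linkS4class{DesignSpec} for the simulation.
#' @return invisibly, a list with every stage's in-memory result and the
#'   `summary` written to JSON.
#' @examples
#' \donttest{
#' res <- runPipeline(pipelineConfig(seed = 11),
#'                    outDir = tempfile("pipe"),
#'                    design = designSpec(nGenes = 200))
#' res$summary$network$connectors
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        design = designSpec()) {
    methods::validObject(config)
    seed <- config@seed
    alpha <- config@deAlpha

    se <- makeCounts(design, seed = childSeed(seed, 10))
    truth <- as.data.frame(rowData(se))

    flagged <- flagOutlierControls(se, marker = "yki",
                                   k = config@outlierMadK)
    keep <- !colnames(se) %in% flagged
    seClean <- se[, keep]

    meta <- as.data.frame(colData(seClean))
    subDE <- function(cells, stages) {
        seClean[, meta$cell_type %in% cells & meta$stage %in% stages]
    }
    de <- list(
        germ_hpo = waldDE(subDE("germ", c("mid", "late")),
                          contrast = c("genotype", "hpo_RNAi", "control"),
                          alpha = alpha, covariates = "stage"),
        germ_yki = waldDE(subDE("germ", c("mid", "late")),
                          contrast = c("genotype", "yki_RNAi", "control"),
                          alpha = alpha, covariates = "stage"),
        soma_hpo = waldDE(subDE("soma", c("early", "mid", "late")),
                          contrast = c("genotype", "hpo_RNAi", "control"),
                          alpha = alpha, covariates = "stage"),
        soma_yki = waldDE(subDE("soma", c("early", "mid", "late")),
                          contrast = c("genotype", "yki_RNAi", "control"),
                          alpha = alpha, covariates = "stage"))
    deSummary <- lapply(de, deCounts)
    excess <- lapply(deSummary, function(d)
        if (d$nDown > 0) updownExcess(d$nUp, d$nDown)$percent
        else NA_real_)

    vst <- vstTransform(seClean)
    pca <- pcaExpression(vst, nComponents = 5)
    r2 <- factorVarianceAttribution(pca$scores,
                                    as.data.frame(colData(seClean)),
                                    "cell_type")

    partGerm <- classifyDEOverlap(de$germ_hpo, de$germ_yki,
                                  labels = c("germ_hpo", "germ_yki"))
    partSoma <- classifyDEOverlap(de$soma_hpo, de$soma_yki,
                                  labels = c("soma_hpo", "soma_yki"))

    sharedGermDown <- partitionSets(partGerm)$sharedDown
    gsets <- makeGeneSets(truth, seed = childSeed(seed, 12))
    enrich <- if (length(sharedGermDown) >= 2)
        hypergeomEnrich(sharedGermDown, gsets$sets, gsets$universe,
                        minSetSize = config@goMinSetSize,
                        padjCutoff = config@goPadjCutoff)
    else NULL

    annotation <- makeAnnotation(design@nGenes,
                                 seed = childSeed(seed, 13))
    names(annotation) <- truth$gene_id
    mcols(annotation)$gene_id <- truth$gene_id
    peakSets <- lapply(1:3, function(i)
        makePeaks(annotation, nPeaks = 800, promoterFraction = 0.72,
                  flank = config@promoterFlank,
                  seed = childSeed(seed, 13 + i)))
    names(peakSets) <- paste0("chip", 1:3)
    assigned <- lapply(peakSets, assignPromoter, genes = annotation,
                       flank = config@promoterFlank)
    intersection <- targetSetsIntersection(
        lapply(assigned, `[[`, "targetGenes"))
    targets <- assigned[[1]]$targetGenes
    overlapStats <- targetOverlapStats(de$germ_hpo, targets)

    nw <- makeNetwork(seed = childSeed(seed, 20))
    net <- buildNetwork(tfgene = nw$tfgene, ppi = nw$ppi)
    conn <- enumerateConnectors(net, "hpo", "yki")

    summary <- list(
        thresholds = list(deAlpha = alpha,
                          promoterFlank = config@promoterFlank,
                          goMinSetSize = config@goMinSetSize,
                          goPadjCutoff = config@goPadjCutoff,
                          keggPadjCutoff = config@keggPadjCutoff,
                          outlierMadK = config@outlierMadK,
                          seed = seed),
        nLibraries = ncol(se),
        outliersFlagged = as.list(flagged),
        de = deSummary,
        updownExcessPercent = excess,
        overlap = list(
            germ = list(counts = as.list(partitionCounts(partGerm)),
                        sharedPercent = sharedFraction(partGerm)$percent),
            soma = list(counts = as.list(partitionCounts(partSoma)),
                        sharedPercent = sharedFraction(partSoma)$percent)),
        pca = list(varFraction = round(pca$varFraction[1:5], 6),
                   cellTypeR2PC1 = round(unname(r2[1]), 6)),
        enrichment = list(
            nEnriched = if (is.null(enrich)) 0L else sum(enrich$enriched),
            topSet = if (!is.null(enrich) && nrow(enrich))
                enrich$set[1] else NA_character_),
        peaks = list(
            promoterFraction = lapply(assigned, `[[`, "fraction"),
            intersection = as.list(intersection$counts)),
        targetOverlap = overlapStats[c("downInTargets",
                                       "targetsDownFraction")],
        network = list(summary = networkSummary(net),
                       connectors = as.list(conn$connectors),
                       pathLength = conn$length,
                       uniqueConnector = conn$unique))

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeCounts(assay(se, "counts"), file.path(outDir, "counts.tsv"))
        writeMetadata(as.data.frame(colData(se)),
                      file.path(outDir, "metadata.tsv"))
        for (nm in names(de))
            writeDEResult(de[[nm]], file.path(outDir,
                                              paste0("de_", nm, ".tsv")))
        if (!is.null(enrich))
            utils::write.table(enrich,
                file.path(outDir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
        utils::write.table(assigned[[1]]$assignments,
            file.path(outDir, "peak_assignments_chip1.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        writeEdges(as.data.frame(networkEdges(net)),
                   file.path(outDir, "network_edges.tsv"))
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             na = "null")
    }
    invisible(list(se = se, flagged = flagged, de = de,
                   partitions = list(germ = partGerm, soma = partSoma),
                   pca = pca, cellTypeR2 = r2, enrichment = enrich,
                   peaks = peakSets, assigned = assigned,
                   intersection = intersection, network = net,
                   connectors = conn, summary = summary))
}
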