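#' @include utils.R
NULL

#' Read and write gene-level count matrices
#'
#' `readCounts()` reads a genes x samples count matrix from a tab-separated
#' file (first column gene IDs, header row sample IDs) or, for paths ending
#' in `.mtx`, from a MatrixMarket triplet file with sidecar gene/sample
#' name files. `writeCounts()` writes the same formats; a write-then-read
#' round trip reproduces the matrix exactly.
#'
#' Parsers validate rather than coerce: duplicate gene or sample IDs,
#' negative, non-integral or non-numeric entries raise an error naming the
#' offending file line.
#'
#' @param path file to read/write. `.mtx` selects MatrixMarket.
#' @param counts integer matrix with gene row names and sample column
#'   names.
#' @param genesPath,samplesPath sidecar name files for MTX mode; default
#'   `<path>.genes.txt` / `<path>.samples.txt`.
#' @return `readCounts()`: an integer matrix with dimnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(0:5, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' writeCounts(m, tf)
#' stopifnot(identical(readCounts(tf), m))
#' @export
readCounts <- function(path, genesPath = paste0(path, ".genes.txt"),
                       samplesPath = paste0(path, ".samples.txt")) {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (grepl("\\.mtx$", path)) {
        m <- as.matrix(Matrix::readMM(path))
        genes <- readLines(genesPath)
        samples <- readLines(samplesPath)
        if (length(genes) != nrow(m) || length(samples) != ncol(m))
            stop("MTX dimensions do not match sidecar name files")
        dimnames(m) <- list(genes, samples)
        storage.mode(m) <- "integer"
        return(assertCountMatrix(m))
    }
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2)
        stop("count table needs a gene ID column plus >= 1 sample column")
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) {
        bad <- which(apply(tab[, -1, drop = FALSE], 1,
                           function(r) any(is.na(suppressWarnings(
                               as.numeric(r))))))
        stop("non-numeric count at line ", bad[1] + 1L, " of ", path)
    }
    if (any(is.na(m) | m < 0 | m != round(m))) {
        bad <- which(apply(m, 1, function(r)
            any(is.na(r) | r < 0 | r != round(r))))
        stop("negative, missing or non-integral count at line ",
             bad[1] + 1L, " of ", path)
    }
    if (anyDuplicated(ids)) {
        bad <- which(duplicated(ids))
        stop("duplicate gene ID '", ids[bad[1]], "' at line ",
             bad[1] + 1L, " of ", path)
    }
    rownames(m) <- ids
    storage.mode(m) <- "integer"
    assertCountMatrix(m)
}

#' @rdname readCounts
#' @export
writeCounts <- function(counts, path,
                        genesPath = paste0(path, ".genes.txt"),
                        samplesPath = paste0(path, ".samples.txt")) {
    assertCountMatrix(counts)
    if (grepl("\\.mtx$", path)) {
        Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
        writeLines(rownames(counts), genesPath)
        writeLines(colnames(counts), samplesPath)
    } else {
        tab <- data.frame(gene_id = rownames(counts), counts,
                          check.names = FALSE)
        utils::write.table(tab, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read and write sample metadata tables
#'
#' Tab-separated table with a `sample_id` first column and per-sample
#' factors (`cell_type`, `stage`, `genotype`, `replicate`).
#'
#' @param path file to read/write.
#' @param meta data.frame with sample row names.
#' @return `readMetadata()`: a data.frame with sample IDs as row names.
#' @export
readMetadata <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (colnames(tab)[1] != "sample_id")
        stop("metadata must start with a sample_id column")
    if (anyDuplicated(tab$sample_id))
        stop("duplicate sample IDs in ", path)
    rownames(tab) <- tab$sample_id
    tab[, -1, drop = FALSE]
}

#' @rdname readMetadata
#' @export
writeMetadata <- function(meta, path) {
    tab <- data.frame(sample_id = rownames(meta), meta, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read and write gene annotations (GTF)
#'
#' Gene models travel as GTF on disk (1-based, closed intervals, a
#' `gene_id` attribute) and as a named `GRanges` in memory, the package's
#' single internal interval representation. The TSS is derived as the
#' start on `+` and the end on `-`; unstranded records are rejected.
#'
#' @param path GTF file.
#' @param genes `GRanges` named by gene ID with strand `+`/`-`.
#' @return `readGTF()`: a `GRanges` named by `gene_id`.
#' @export
readGTF <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% colnames(mcols(gr)) && any(gr$type == "gene"))
        gr <- gr[gr$type == "gene"]
    if (!"gene_id" %in% colnames(mcols(gr)))
        stop("GTF records lack a gene_id attribute: ", path)
    ids <- as.character(gr$gene_id)
    if (anyDuplicated(ids))
        stop("duplicate gene_id '", ids[which(duplicated(ids))[1]],
             "' in ", path)
    if (any(as.character(strand(gr)) == "*"))
        stop("unstranded gene records in ", path)
    names(gr) <- ids
    mcols(gr) <- S4Vectors::DataFrame(gene_id = ids)
    gr
}

#' @rdname readGTF
#' @export
writeGTF <- function(genes, path) {
    if (is.null(names(genes)))
        stop("genes must be named by gene ID")
    gr <- granges(genes)
    mcols(gr) <- S4Vectors::DataFrame(
        source = "HippoConnect", type = "gene",
        gene_id = names(genes))
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}

#' Read and write peak intervals (BED6)
#'
#' BED is the only 0-based, half-open surface; rtracklayer converts to the
#' 1-based closed `GRanges` convention used everywhere in memory, so a
#' BED interval `[100, 200)` becomes a width-100 range.
#'
#' @param path BED file.
#' @param peaks `GRanges`, optionally named and with a numeric `score`.
#' @return `readBED()`: a `GRanges` named by the BED name field (or
#'   `peak_<i>` when absent).
#' @export
readBED <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    gr <- rtracklayer::import(path, format = "bed")
    nm <- if ("name" %in% colnames(mcols(gr))) as.character(gr$name)
          else paste0("peak_", seq_along(gr))
    nm[is.na(nm)] <- paste0("peak_", which(is.na(nm)))
    names(gr) <- nm
    gr
}

#' @rdname readBED
#' @export
writeBED <- function(peaks, path) {
    gr <- granges(peaks)
    mcols(gr) <- S4Vectors::DataFrame(
        name = if (is.null(names(peaks))) paste0("peak_", seq_along(peaks))
               else names(peaks),
        score = if ("score" %in% colnames(mcols(peaks)))
                    mcols(peaks)$score else 0L)
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}

#' Read and write typed regulatory edge lists
#'
#' Tab-separated with columns `source`, `target`, `type` (`tfgene` or
#' `ppi`) and `provenance`; a missing provenance column defaults to
#' `"user"`.
#'
#' @param path edge-list TSV.
#' @param edges data.frame with the columns above.
#' @return `readEdges()`: a data.frame with the four columns.
#' @export
readEdges <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!all(c("source", "target", "type") %in% colnames(tab)))
        stop("edge list needs columns source, target, type: ", path)
    if (!"provenance" %in% colnames(tab))
        tab$provenance <- "user"
    bad <- which(!tab$type %in% c("tfgene", "ppi"))
    if (length(bad))
        stop("invalid edge type '", tab$type[bad[1]], "' at line ",
             bad[1] + 1L, " of ", path)
    tab[, c("source", "target", "type", "provenance")]
}

#' @rdname readEdges
#' @export
writeEdges <- function(edges, path) {
    utils::write.table(as.data.frame(edges)[, c("source", "target", "type",
                                                "provenance")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Construct or read a pipeline configuration
#'
#' `pipelineConfig()` builds a validated \linkS4class{PipelineConfig} from
#' named thresholds (defaults are the workflow's canonical values);
#' `readConfig()` reads the same fields from a YAML file, with omitted
#' fields falling back to the defaults.
#'
#' @param deAlpha,promoterFlank,goMinSetSize,goPadjCutoff,keggPadjCutoff,outlierMadK,seed
#'   see \linkS4class{PipelineConfig}.
#' @param path YAML file with any subset of the config field names.
#' @return a `PipelineConfig`.
#' @examples
#' pipelineConfig(deAlpha = 0.05, seed = 7)
#' @export
pipelineConfig <- function(deAlpha = 0.05, promoterFlank = 1500,
                           goMinSetSize = 30, goPadjCutoff = 0.01,
                           keggPadjCutoff = 0.05, outlierMadK = 3,
                           seed = 1L) {
    methods::new("PipelineConfig", deAlpha = deAlpha,
                 promoterFlank = promoterFlank,
                 goMinSetSize = goMinSetSize, goPadjCutoff = goPadjCutoff,
                 keggPadjCutoff = keggPadjCutoff, outlierMadK = outlierMadK,
                 seed = seed)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- c("deAlpha", "promoterFlank", "goMinSetSize", "goPadjCutoff",
               "keggPadjCutoff", "outlierMadK", "seed")
    extra <- setdiff(names(vals), known)
    if (length(extra))
        stop("unknown config fields: ", paste(extra, collapse = ", "))
    do.call(pipelineConfig, vals)
}
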