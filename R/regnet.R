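#' @include AllClasses.R AllGenerics.R
NULL

#' Build a heterogeneous regulatory network
#'
#' Merges a directed TF-gene edge list, an undirected PPI edge list and
#' any number of ChIP-derived target lists (added as directed `tfgene`
#' edges carrying their own provenance) into a single typed network.
#' Direction encodes regulatory logic: TFs regulate their targets, not
#' vice versa, so `tfgene` edges are traversable source to target only,
#' while PPI edges are traversable both ways. PPI endpoint pairs are
#' canonicalised (sorted) and duplicate `(source, target, type)` triples
#' are dropped; self-loops are kept but counted in the build summary.
#'
#' @param tfgene data.frame with `source`, `target` (and optional
#'   `provenance`, default `"droid-like"`).
#' @param ppi data.frame with `source`, `target` (optional `provenance`).
#' @param chip optional named list of data.frames with `source`,
#'   `target`; each is added as `tfgene` edges with provenance equal to
#'   its list name (e.g. `chip-yki`).
#' @return a \linkS4class{RegulatoryNetwork}; [networkSummary()] returns
#'   node/edge counts, duplicates dropped and self-loop count.
#' @examples
#' net <- buildNetwork(
#'     tfgene = data.frame(source = "chinmo", target = c("yki", "hpo")),
#'     ppi = data.frame(source = "hpo", target = "chinmo"))
#' net
#' @export
buildNetwork <- function(tfgene = NULL, ppi = NULL, chip = NULL) {
    pieces <- list()
    addPiece <- function(df, type, defaultProv) {
        if (is.null(df) || !nrow(df)) return(NULL)
        df <- as.data.frame(df)
        if (!all(c("source", "target") %in% colnames(df)))
            stop("edge lists need source and target columns")
        prov <- if ("provenance" %in% colnames(df)) df$provenance
                else defaultProv
        data.frame(source = as.character(df$source),
                   target = as.character(df$target),
                   type = type, provenance = prov,
                   stringsAsFactors = FALSE)
    }
    pieces$tf <- addPiece(tfgene, "tfgene", "droid-like")
    pieces$ppi <- addPiece(ppi, "ppi", "droid-like")
    if (!is.null(chip)) {
        if (is.data.frame(chip)) chip <- list(chip = chip)
        for (nm in names(chip))
            pieces[[paste0("chip_", nm)]] <-
                addPiece(chip[[nm]], "tfgene", nm)
    }
    ed <- do.call(rbind, pieces)
    if (is.null(ed))
        ed <- data.frame(source = character(), target = character(),
                         type = character(), provenance = character())
    nIn <- nrow(ed)
    if (nIn) {
        flip <- ed$type == "ppi" & ed$source > ed$target
        tmp <- ed$source[flip]
        ed$source[flip] <- ed$target[flip]
        ed$target[flip] <- tmp
        dup <- duplicated(paste(ed$source, ed$target, ed$type, sep = "\r"))
        ed <- ed[!dup, , drop = FALSE]
    }
    selfLoops <- sum(ed$source == ed$target)
    edges <- S4Vectors::DataFrame(ed, row.names = NULL)
    nodes <- sort(unique(c(ed$source, ed$target)))
    metadata(edges)$summary <- list(
        nodes = length(nodes),
        edgesByType = as.list(table(ed$type)),
        duplicatesDropped = nIn - nrow(ed),
        selfLoops = selfLoops)
    methods::new("RegulatoryNetwork", edges = edges, nodes = nodes)
}

#' @rdname buildNetwork
#' @param net a `RegulatoryNetwork`.
#' @export
networkSummary <- function(net) metadata(net@edges)$summary

# outgoing-adjacency list of the directed expansion (ppi both ways);
# self-loops are dropped for traversal
netAdjacency <- function(net) {
    ed <- as.data.frame(net@edges)
    ed <- ed[ed$source != ed$target, , drop = FALSE]
    src <- ed$source; tgt <- ed$target
    ppi <- ed$type == "ppi"
    from <- c(src, tgt[ppi])
    to <- c(tgt, src[ppi])
    adj <- split(to, factor(from, levels = net@nodes))
    lapply(adj, unique)
}

#' All shortest regulatory paths between two genes
#'
#' Breadth-first search on the directed expansion of the network (`tfgene`
#' edges usable source to target only, `ppi` edges usable both ways)
#' returning the minimal edge count and every distinct shortest node
#' sequence, ordered lexicographically. Self-loops are ignored. When the
#' target is unreachable the length is `Inf` with an empty path list.
#'
#' @param net a \linkS4class{RegulatoryNetwork}.
#' @param src,dst node identifiers (must exist in the network).
#' @param maxPaths cap on enumerated paths (default 1000); exceeding it
#'   sets `truncated = TRUE`.
#' @return list with `length` (edges; 0 when `src == dst`, `Inf` when
#'   unreachable), `paths` (list of node character vectors) and
#'   `truncated`.
#' @examples
#' net <- buildNetwork(
#'     tfgene = data.frame(source = c("chinmo", "chinmo", "yki"),
#'                         target = c("yki", "hpo", "chinmo")),
#'     ppi = data.frame(source = "hpo", target = "chinmo"))
#' shortestRegulatoryPath(net, "hpo", "yki")
#' @export
shortestRegulatoryPath <- function(net, src, dst, maxPaths = 1000) {
    missing <- setdiff(c(src, dst), net@nodes)
    if (length(missing))
        stop("unknown node(s): ", paste(missing, collapse = ", "))
    if (src == dst)
        return(list(length = 0, paths = list(src), truncated = FALSE))
    adj <- netAdjacency(net)

    dist <- stats::setNames(rep(Inf, length(net@nodes)), net@nodes)
    dist[src] <- 0
    frontier <- src
    while (length(frontier) && !is.finite(dist[dst])) {
        nxt <- unique(unlist(adj[frontier], use.names = FALSE))
        nxt <- nxt[!is.finite(dist[nxt])]
        dist[nxt] <- dist[frontier[1]] + 1
        frontier <- nxt
    }
    if (!is.finite(dist[dst]))
        return(list(length = Inf, paths = list(), truncated = FALSE))
    L <- as.numeric(dist[dst])

    # predecessor map restricted to BFS levels, then backward enumeration
    ed <- as.data.frame(net@edges)
    ed <- ed[ed$source != ed$target, , drop = FALSE]
    ppi <- ed$type == "ppi"
    from <- c(ed$source, ed$target[ppi])
    to <- c(ed$target, ed$source[ppi])
    onLevel <- is.finite(dist[from]) & is.finite(dist[to]) &
        dist[from] + 1 == dist[to]
    # multi-edges of different type collapse to one traversal arc
    pred <- lapply(split(from[onLevel],
                         factor(to[onLevel], levels = net@nodes)), unique)

    truncated <- FALSE
    paths <- list()
    walk <- function(node, suffix) {
        if (truncated) return()
        if (node == src) {
            if (length(paths) >= maxPaths) {
                truncated <<- TRUE
                return()
            }
            paths[[length(paths) + 1L]] <<- c(src, suffix)
            return()
        }
        for (u in pred[[node]]) walk(u, c(node, suffix))
    }
    walk(dst, character())

    if (length(paths) > 1) {
        m <- do.call(rbind, paths)
        ord <- do.call(order, as.data.frame(m, stringsAsFactors = FALSE))
        paths <- paths[ord]
    }
    list(length = L, paths = paths, truncated = truncated)
}

#' Enumerate connector genes on the shortest regulatory paths
#'
#' Connectors are the interior nodes of all shortest paths between `src`
#' and `dst`. The `unique` flag is `TRUE` exactly when there is a single
#' connector at shortest length 2 — a sole two-step intermediary. A
#' direct `src -> dst` edge is reported as length 1 with an empty
#' connector set.
#'
#' @inheritParams shortestRegulatoryPath
#' @return list with `connectors` (sorted character vector), `unique`,
#'   `length` and `truncated`.
#' @export
enumerateConnectors <- function(net, src, dst, maxPaths = 1000) {
    sp <- shortestRegulatoryPath(net, src, dst, maxPaths = maxPaths)
    connectors <- character()
    if (is.finite(sp$length) && sp$length >= 2)
        connectors <- sort(unique(unlist(lapply(sp$paths, function(p)
            p[-c(1, length(p))]))))
    list(connectors = connectors,
         unique = sp$length == 2 && length(connectors) == 1,
         length = sp$length, truncated = sp$truncated)
}

#' Overlap between differential expression and a target gene set
#'
#' Two complementary fractions tying knockdown-responsive genes to
#' putative direct targets: (a) the share of significantly downregulated
#' genes that are targets; (b) among significantly differentially
#' expressed genes that are targets, the share that is downregulated.
#' Empty denominators yield 0.
#'
#' @param de a \linkS4class{DEResult}.
#' @param targets character vector of target gene IDs.
#' @return list with `downInTargets` (a) and `targetsDownFraction` (b),
#'   plus the underlying counts.
#' @export
targetOverlapStats <- function(de, targets) {
    sig <- as.logical(de$significant)
    down <- sig & de$log2FC < 0
    genes <- rownames(de)
    downGenes <- genes[down]
    sigTargets <- genes[sig][genes[sig] %in% targets]
    a <- if (length(downGenes))
        mean(downGenes %in% targets) else 0
    b <- if (length(sigTargets))
        mean(sigTargets %in% downGenes) else 0
    list(downInTargets = a, targetsDownFraction = b,
         nDown = length(downGenes), nSigTargets = length(sigTargets))
}
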