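# Independent brute-force oracles used to validate the implementations.

# All simple paths between src and dst by exhaustive DFS on the directed
# expansion of a typed edge list (tfgene one-way, ppi both ways, self
# loops dropped); returns minimal length and all shortest paths sorted
# lexicographically. Intentionally naive.
bruteForcePaths <- function(edges, src, dst) {
    edges <- edges[edges$source != edges$target, , drop = FALSE]
    ppi <- edges$type == "ppi"
    from <- c(edges$source, edges$target[ppi])
    to <- c(edges$target, edges$source[ppi])
    nodes <- unique(c(from, to, src, dst))
    adj <- lapply(setNames(nodes, nodes),
                  function(u) unique(to[from == u]))
    found <- list()
    dfs <- function(path) {
        u <- path[length(path)]
        if (u == dst) {
            found[[length(found) + 1L]] <<- path
            return()
        }
        for (v in adj[[u]])
            if (!v %in% path) dfs(c(path, v))
    }
    if (src == dst) return(list(length = 0, paths = list(src)))
    dfs(src)
    if (!length(found)) return(list(length = Inf, paths = list()))
    lens <- vapply(found, length, integer(1)) - 1L
    L <- min(lens)
    sp <- found[lens == L]
    if (length(sp) > 1) {
        m <- do.call(rbind, sp)
        sp <- sp[do.call(order, as.data.frame(m))]
    }
    list(length = L, paths = sp)
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# C(N, n) draws from a universe with K successes. Feasible for N <= 20.
enumHyperTail <- function(N, K, n, k) {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)  # successes are elements 1..K
    mean(hits >= k)
}

# Direct Benjamini-Hochberg step-up formula (no p.adjust).
bhDirect <- function(p) {
    m <- length(p)
    o <- order(p)
    ranked <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(ranked)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
}

# Build a DEResult directly from vectors (for toy partition tests).
makeDEResultFixture <- function(genes, lfc, padj, alpha = 0.05) {
    df <- S4Vectors::DataFrame(
        baseMean = rep(100, length(genes)), log2FC = lfc,
        SE = rep(0.1, length(genes)), stat = lfc / 0.1,
        pvalue = pmin(padj, 1), padj = padj,
        significant = !is.na(padj) & padj < alpha,
        row.names = genes)
    out <- methods::new("DEResult", df)
    S4Vectors::metadata(out) <- list(alpha = alpha,
                                     contrast = c("f", "A", "B"))
    out
}

# Random small typed graph for path-oracle comparisons.
randomTypedGraph <- function(nNodes, seed) {
    set.seed(seed)
    nodes <- paste0("n", seq_len(nNodes))
    nTf <- sample(0:(2 * nNodes), 1)
    nPpi <- sample(0:nNodes, 1)
    tf <- if (nTf > 0)
        data.frame(source = sample(nodes, nTf, replace = TRUE),
                   target = sample(nodes, nTf, replace = TRUE))
    else NULL
    pp <- if (nPpi > 0)
        data.frame(source = sample(nodes, nPpi, replace = TRUE),
                   target = sample(nodes, nPpi, replace = TRUE))
    else NULL
    list(tf = tf, ppi = pp, nodes = nodes)
}
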