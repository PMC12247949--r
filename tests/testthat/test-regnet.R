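motifNetwork <- function() {
    buildNetwork(
        tfgene = data.frame(source = c("chinmo", "chinmo", "yki"),
                            target = c("yki", "hpo", "chinmo")),
        ppi = data.frame(source = "hpo", target = "chinmo"))
}

test_that("network construction deduplicates by typed edge identity", {
    net <- buildNetwork(
        tfgene = data.frame(source = c("X", "X"), target = c("Y", "Y")),
        ppi = data.frame(source = "X", target = "Y"))
    expect_equal(nrow(networkEdges(net)), 2)
    expect_setequal(as.character(networkEdges(net)$type),
                    c("tfgene", "ppi"))
    expect_equal(networkSummary(net)$duplicatesDropped, 1)

    empty <- buildNetwork()
    expect_length(networkNodes(empty), 0)
    expect_equal(nrow(networkEdges(empty)), 0)

    # ppi canonical storage: (B, A) and (A, B) are one edge
    net2 <- buildNetwork(ppi = data.frame(source = c("B", "A"),
                                          target = c("A", "B")))
    expect_equal(nrow(networkEdges(net2)), 1)
    expect_identical(as.character(networkEdges(net2)$source), "A")
})

test_that("random multiset inputs match exhaustive set construction", {
    set.seed(15)
    nodes <- paste0("n", 1:15)
    tf <- data.frame(source = sample(nodes, 60, replace = TRUE),
                     target = sample(nodes, 60, replace = TRUE))
    pp <- data.frame(source = sample(nodes, 40, replace = TRUE),
                     target = sample(nodes, 40, replace = TRUE))
    net <- buildNetwork(tfgene = tf, ppi = pp)
    # brute-force: unique typed keys with canonical ppi pairs
    tfKey <- unique(paste(tf$source, tf$target))
    ppKey <- unique(apply(pp, 1, function(r)
        paste(sort(c(r[["source"]], r[["target"]])), collapse = " ")))
    ed <- networkEdges(net)
    expect_equal(sum(ed$type == "tfgene"), length(tfKey))
    expect_equal(sum(ed$type == "ppi"), length(ppKey))
    expect_setequal(networkNodes(net),
                    unique(c(tf$source, tf$target, pp$source, pp$target)))
})

test_that("chip target lists join as tfgene edges with provenance", {
    net <- buildNetwork(
        tfgene = data.frame(source = "tf1", target = "g1"),
        chip = list("chip-yki" = data.frame(source = "yki",
                                            target = c("g1", "g2"))))
    ed <- networkEdges(net)
    expect_equal(sum(ed$provenance == "chip-yki"), 2)
    expect_true(all(ed$type == "tfgene"))
})

test_that("the planted motif has a single two-step path through chinmo", {
    net <- motifNetwork()
    sp <- shortestRegulatoryPath(net, "hpo", "yki")
    expect_equal(sp$length, 2)
    expect_length(sp$paths, 1)
    expect_identical(sp$paths[[1]], c("hpo", "chinmo", "yki"))

    conn <- enumerateConnectors(net, "hpo", "yki")
    expect_identical(conn$connectors, "chinmo")
    expect_true(conn$unique)

    # a second parallel connector breaks uniqueness
    net2 <- buildNetwork(
        tfgene = data.frame(source = c("chinmo", "chinmo", "yki", "w"),
                            target = c("yki", "hpo", "chinmo", "yki")),
        ppi = data.frame(source = c("hpo", "hpo"),
                         target = c("chinmo", "w")))
    conn2 <- enumerateConnectors(net2, "hpo", "yki")
    expect_setequal(conn2$connectors, c("chinmo", "w"))
    expect_false(conn2$unique)
})

test_that("path search respects direction, self and degenerate cases", {
    # tfgene Y -> X alone provides no X -> Y route
    net <- buildNetwork(tfgene = data.frame(source = "Y", target = "X"))
    sp <- shortestRegulatoryPath(net, "X", "Y")
    expect_equal(sp$length, Inf)
    expect_length(sp$paths, 0)

    same <- shortestRegulatoryPath(net, "X", "X")
    expect_equal(same$length, 0)
    expect_identical(same$paths[[1]], "X")

    expect_error(shortestRegulatoryPath(net, "X", "nope"),
                 "unknown node")

    # a direct edge is length 1 with an empty connector set
    direct <- buildNetwork(tfgene = data.frame(source = "A",
                                               target = "B"))
    conn <- enumerateConnectors(direct, "A", "B")
    expect_equal(conn$length, 1)
    expect_length(conn$connectors, 0)
    expect_false(conn$unique)

    # self-loops are ignored during search
    loop <- buildNetwork(tfgene = data.frame(source = c("A", "A"),
                                             target = c("A", "B")))
    expect_equal(shortestRegulatoryPath(loop, "A", "B")$length, 1)
})

test_that("removing the connector disconnects the pure motif", {
    ed <- as.data.frame(networkEdges(motifNetwork()))
    keep <- ed$source != "chinmo" & ed$target != "chinmo"
    net <- buildNetwork(
        tfgene = ed[keep & ed$type == "tfgene", ],
        ppi = ed[keep & ed$type == "ppi", ])
    nodes <- unique(c(networkNodes(net), "hpo", "yki"))
    # rebuild with isolated endpoints present
    net <- buildNetwork(
        tfgene = rbind(ed[keep & ed$type == "tfgene",
                          c("source", "target")],
                       data.frame(source = c("hpo", "yki"),
                                  target = c("hpo", "yki"))))
    sp <- shortestRegulatoryPath(net, "hpo", "yki")
    expect_equal(sp$length, Inf)
})

test_that("BFS agrees with exhaustive simple-path enumeration", {
    for (s in 1:50) {
        g <- randomTypedGraph(sample(4:12, 1), seed = s)
        net <- buildNetwork(tfgene = g$tf, ppi = g$ppi)
        present <- networkNodes(net)
        if (length(present) < 2) next
        pick <- sample(present, 2)
        got <- shortestRegulatoryPath(net, pick[1], pick[2],
                                      maxPaths = 1e6)
        ref <- bruteForcePaths(as.data.frame(networkEdges(net)),
                               pick[1], pick[2])
        expect_equal(got$length, ref$length)
        expect_equal(got$paths, ref$paths)
        # every returned path has exactly `length` edges
        if (is.finite(got$length))
            expect_true(all(vapply(got$paths, length, integer(1)) ==
                            got$length + 1))
        conn <- enumerateConnectors(net, pick[1], pick[2],
                                    maxPaths = 1e6)
        refConn <- sort(unique(unlist(lapply(ref$paths, function(p)
            p[-c(1, length(p))]))))
        if (is.null(refConn)) refConn <- character()
        expect_identical(conn$connectors, refConn)
    }
})

test_that("path enumeration caps and flags truncation", {
    # layered graph with 3 x 3 parallel routes -> 9 shortest paths
    tf <- rbind(expand.grid(source = "s", target = paste0("m", 1:3)),
                expand.grid(source = paste0("m", 1:3), target = "t"))
    net <- buildNetwork(tfgene = tf)
    full <- shortestRegulatoryPath(net, "s", "t", maxPaths = 100)
    expect_length(full$paths, 3)
    capped <- shortestRegulatoryPath(net, "s", "t", maxPaths = 2)
    expect_true(capped$truncated)
    expect_length(capped$paths, 2)
})

test_that("target overlap fractions match exhaustive counting", {
    de <- makeDEResultFixture(paste0("g", 1:10),
                              lfc = c(-2, -1, 1, 2, -3, 1, -1, 2, -2, 1),
                              padj = c(0.01, 0.02, 0.01, 0.5, 0.03, 0.6,
                                       0.01, 0.02, 0.7, 0.04))
    # significant: g1- g2- g3+ g5- g7- g8+ g10+ ; down: g1 g2 g5 g7
    down <- c("g1", "g2", "g5", "g7")
    stats <- targetOverlapStats(de, down)
    expect_equal(stats$downInTargets, 1)

    none <- targetOverlapStats(de, c("g4", "g9"))  # not significant
    expect_equal(none$downInTargets, 0)
    expect_equal(none$targetsDownFraction, 0)

    mixed <- targetOverlapStats(de, c("g1", "g3", "g8"))
    expect_equal(mixed$downInTargets, 1 / 4)
    expect_equal(mixed$targetsDownFraction, 1 / 3)

    set.seed(30)
    genes <- paste0("g", 1:200)
    de2 <- makeDEResultFixture(genes, lfc = rnorm(200),
                               padj = runif(200))
    targets <- sample(genes, 60)
    st <- targetOverlapStats(de2, targets)
    sig <- genes[de2$significant]
    dn <- genes[de2$significant & de2$log2FC < 0]
    expect_equal(st$downInTargets, mean(dn %in% targets))
    expect_equal(st$targetsDownFraction,
                 mean(intersect(sig, targets) %in% dn))
})
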