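test_that("size factors follow the median-of-ratios definition", {
    m <- matrix(rep(c(10L, 20L, 40L, 80L), 3), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
    expect_equal(unname(computeSizeFactors(m)), c(1, 1, 1))

    a <- c(10L, 20L, 40L, 80L)
    m2 <- cbind(s1 = a, s2 = 2L * a)
    rownames(m2) <- paste0("g", 1:4)
    sf <- computeSizeFactors(m2)
    expect_equal(unname(sf[2] / sf[1]), 2)

    single <- m2[, 1, drop = FALSE]
    expect_equal(unname(computeSizeFactors(single)), 1)
})

test_that("size factors agree with the reference implementation", {
    skip_if_not_installed("DESeq2")
    set.seed(10)
    m <- matrix(rpois(600, 80), 100, 6,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
    storage.mode(m) <- "integer"
    expect_equal(unname(computeSizeFactors(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-10)
})

test_that("degenerate count matrices are handled explicitly", {
    m <- matrix(c(5L, 0L, 0L, 7L), 2, 2,
                dimnames = list(c("g1", "g2"), c("a", "b")))
    expect_error(computeSizeFactors(m), "pseudo")
    sf <- computeSizeFactors(m, allowPseudoReference = TRUE)
    expect_true(all(sf > 0))
})

test_that("the VST stand-in is log2(normalised + 1) and monotone", {
    m <- matrix(c(0L, 3L), 2, 1, dimnames = list(c("g1", "g2"), "s"))
    v <- vstTransform(m, sizeFactors = c(s = 1))
    expect_equal(unname(v[, 1]), c(0, 2))
    # exhaustive monotonicity scan over counts 0..1000
    x <- matrix(0:1000, ncol = 1, dimnames = list(0:1000, "s"))
    storage.mode(x) <- "integer"
    v <- vstTransform(x, sizeFactors = c(s = 1.7))
    expect_true(all(diff(v[, 1]) > 0))
})

test_that("dispersion estimation recovers planted values", {
    grp <- factor(rep(c("a", "b"), each = 10))
    # constant genes: zero variance, zero dispersion
    const <- matrix(50L, 200, 20,
                    dimnames = list(paste0("g", 1:200), paste0("s", 1:20)))
    a <- estimateDispersion(const, grp, sizeFactors = rep(1, 20))
    expect_true(all(a < 1e-6))

    # Poisson data: median estimate near zero
    set.seed(11)
    pois <- matrix(rpois(500 * 20, 100), 500, 20,
                   dimnames = list(paste0("g", 1:500), paste0("s", 1:20)))
    storage.mode(pois) <- "integer"
    a <- estimateDispersion(pois, grp, sizeFactors = rep(1, 20))
    expect_lt(median(a), 0.01)

    # planted alpha = 0.2, 10 replicates per group
    set.seed(12)
    nb <- matrix(rnbinom(500 * 20, mu = 200, size = 1 / 0.2), 500, 20,
                 dimnames = list(paste0("g", 1:500), paste0("s", 1:20)))
    storage.mode(nb) <- "integer"
    a <- estimateDispersion(nb, grp, sizeFactors = rep(1, 20))
    expect_gt(median(a), 0.1)
    expect_lt(median(a), 0.3)
})

test_that("dispersion falls back to the trend without replication", {
    m <- matrix(rpois(20, 50), 10, 2,
                dimnames = list(paste0("g", 1:10), c("a", "b")))
    storage.mode(m) <- "integer"
    expect_warning(a <- estimateDispersion(m, factor(c("x", "y")),
                                           sizeFactors = c(1, 1)),
                   "trend-only")
    expect_true(all(a >= 0))
})

test_that("the Wald contrast is antisymmetric and scale equivariant", {
    se <- makeCounts(designSpec(nGenes = 40), seed = 5)
    germ <- se[, se$cell_type == "germ" & se$stage == "mid"]
    ab <- waldDE(germ, contrast = c("genotype", "hpo_RNAi", "control"))
    ba <- waldDE(germ, contrast = c("genotype", "control", "hpo_RNAi"))
    expect_equal(ab$log2FC, -ba$log2FC, tolerance = 1e-8)
    expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-6)

    # multiplying one sample's counts scales its size factor by c
    # relative to every other sample (the geometric-mean reference
    # absorbs a common c^(1/m)) and leaves the fit unchanged
    cm <- SummarizedExperiment::assay(germ) + 1L  # all-positive fixture
    meta <- as.data.frame(SummarizedExperiment::colData(germ))
    cm2 <- cm
    cm2[, 1] <- 3L * cm2[, 1]
    sf1 <- computeSizeFactors(cm)
    sf2 <- computeSizeFactors(cm2)
    expect_equal(unname((sf2[1] / sf2[-1]) / (sf1[1] / sf1[-1])),
                 rep(3, ncol(cm) - 1), tolerance = 1e-12)
    # the fit is stable under the rescaling: the normalised means are
    # unchanged, but the scaled sample's contribution to the likelihood
    # carries c times the raw counts, so estimates agree closely rather
    # than identically
    disp <- estimateDispersion(cm, factor(meta$genotype), sf1)
    r1 <- waldDE(cm, meta, contrast = c("genotype", "hpo_RNAi", "control"),
                 dispersions = disp)
    r2 <- waldDE(cm2, meta, contrast = c("genotype", "hpo_RNAi", "control"),
                 dispersions = disp)
    expect_equal(r1$log2FC, r2$log2FC, tolerance = 0.02)
    expect_true(all(abs(r1$pvalue - r2$pvalue) < 0.02))
    expect_identical(r1$significant, r2$significant)
})

test_that("identical groups give a null result for a single gene", {
    y <- rep(c(12L, 30L, 7L, 21L, 18L, 25L, 9L, 14L, 19L, 22L), 2)
    cm <- matrix(y, 1, 20,
                 dimnames = list("g1", paste0("s", 1:20)))
    meta <- data.frame(genotype = rep(c("control", "hpo_RNAi"), each = 10),
                       row.names = colnames(cm))
    res <- waldDE(cm, meta, contrast = c("genotype", "hpo_RNAi", "control"),
                  sizeFactors = setNames(rep(1, 20), colnames(cm)))
    expect_lt(abs(res$log2FC), 0.2)
    expect_gt(res$pvalue, 0.5)
})

test_that("a strong planted knockdown is detected at the right scale", {
    # scaled simulation mirroring a -4.1 log2FC self-knockdown
    set.seed(71)
    n <- 60
    truth <- data.frame(gene_id = c("hpo", sprintf("g%03d", 2:n)),
                        class = "null", baseline = 300, dispersion = 0.05,
                        lfc_germ_hpo = c(-4.1, rep(0, n - 1)))
    des <- designSpec(nGenes = n, replicates = data.frame(
        cell_type = "germ", stage = "mid",
        genotype = c("control", "hpo_RNAi"), n = 3))
    se <- makeCounts(des, truth = truth, seed = 71, plantOutlier = FALSE)
    res <- waldDE(se, contrast = c("genotype", "hpo_RNAi", "control"))
    expect_gt(res["hpo", "log2FC"], -5.1)
    expect_lt(res["hpo", "log2FC"], -3.1)
    expect_lt(res["hpo", "padj"], 0.05)
})

test_that("the NB fit matches an independent GLM on a fixture", {
    skip_if_not_installed("MASS")
    set.seed(42)
    y <- rnbinom(12, mu = rep(c(50, 200), each = 6), size = 1 / 0.1)
    cm <- matrix(as.integer(y), 1, 12,
                 dimnames = list("g1", paste0("s", 1:12)))
    meta <- data.frame(genotype = rep(c("control", "hpo_RNAi"), each = 6),
                       row.names = colnames(cm))
    sf <- setNames(rep(1, 12), colnames(cm))
    res <- waldDE(cm, meta, contrast = c("genotype", "hpo_RNAi", "control"),
                  sizeFactors = sf,
                  dispersions = c(g1 = 0.1))
    ref <- suppressWarnings(stats::glm(
        y ~ grp, data = data.frame(y = y, grp = meta$genotype),
        family = MASS::negative.binomial(theta = 10)))
    expect_equal(res$log2FC, unname(coef(ref)[2]) / log(2),
                 tolerance = 1e-4)
    # compare against the information-based (unscaled) covariance
    seRef <- sqrt(diag(summary(ref, dispersion = 1)$cov.scaled))[2]
    expect_equal(res$SE, unname(seRef) / log(2), tolerance = 1e-3)
})

test_that("all-zero genes are excluded from the BH family", {
    cm <- rbind(g1 = rep(0L, 6), g2 = c(5L, 8L, 6L, 50L, 60L, 55L))
    colnames(cm) <- paste0("s", 1:6)
    meta <- data.frame(genotype = rep(c("control", "hpo_RNAi"), each = 3),
                       row.names = colnames(cm))
    res <- waldDE(cm, meta, contrast = c("genotype", "hpo_RNAi", "control"),
                  sizeFactors = setNames(rep(1, 6), colnames(cm)))
    expect_true(is.na(res["g1", "pvalue"]))
    expect_true(is.na(res["g1", "padj"]))
    expect_false(res["g1", "significant"])
    # the non-zero gene's padj equals its p (family of size 1)
    expect_equal(res["g2", "padj"], res["g2", "pvalue"])
})

test_that("a confounded design is rejected by name", {
    cm <- matrix(rpois(40, 30), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
    storage.mode(cm) <- "integer"
    meta <- data.frame(genotype = rep(c("control", "hpo_RNAi"), each = 5),
                       batch = rep(c("b1", "b2"), each = 5),
                       row.names = colnames(cm))
    expect_error(waldDE(cm, meta,
                        contrast = c("genotype", "hpo_RNAi", "control"),
                        covariates = "batch"),
                 "full rank")
})

test_that("BH adjustment matches the step-up formula and its properties", {
    expect_equal(unname(bhAdjust(c(0.01, 0.02, 0.03, 0.04))),
                 rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    set.seed(4)
    for (i in 1:5) {
        p <- runif(50)
        adj <- bhAdjust(p)
        expect_true(all(adj >= p) && all(adj <= 1))
        expect_equal(adj, bhDirect(p))
    }
    p <- c(0.5, NA, 0.01)
    adj <- bhAdjust(p)
    expect_true(is.na(adj[2]))
    expect_equal(adj[c(1, 3)], bhDirect(p[c(1, 3)]))
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("outlier controls are flagged by the MAD rule", {
    # construction with known MAD: 9 controls, one suppressed 10x
    marker <- c(1000L, 980L, 1020L, 1010L, 100L, 990L, 1005L, 995L, 1015L)
    cm <- rbind(yki = marker,
                ref = rep(500L, 9))
    colnames(cm) <- paste0("c", 1:9)
    meta <- data.frame(cell_type = rep("germ", 9),
                       genotype = rep("control", 9),
                       row.names = colnames(cm))
    sf <- setNames(rep(1, 9), colnames(cm))
    got <- flagOutlierControls(cm, meta, marker = "yki", k = 3,
                               sizeFactors = sf)
    expect_identical(got, "c5")
    # homogeneous controls: nothing flagged
    cm["yki", 5] <- 1000L
    expect_length(flagOutlierControls(cm, meta, marker = "yki", k = 3,
                                      sizeFactors = sf), 0)
    # k = Inf flags nothing regardless of the data
    cm["yki", 5] <- 1L
    expect_length(flagOutlierControls(cm, meta, marker = "yki", k = Inf,
                                      sizeFactors = sf), 0)
    # fewer than 3 peers cannot be assessed
    expect_warning(
        flagOutlierControls(cm[, 1:2], meta[1:2, , drop = FALSE],
                            marker = "yki", k = 3, sizeFactors = sf[1:2]),
        "fewer than 3")
})
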