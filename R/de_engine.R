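#' @include utils.R
NULL

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed against a geometric-mean
#' pseudo-reference: for each sample the factor is the median over genes of
#' `count / geomean(gene)`, restricted to genes with strictly positive
#' counts in every sample. With a single sample the factor is 1.
#'
#' @param counts integer gene x sample matrix (or a
#'   `SummarizedExperiment` with a `counts` assay).
#' @param allowPseudoReference when no gene is positive in all samples,
#'   fall back to a pseudo-reference computed over each gene's positive
#'   entries only (instead of erroring).
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(1:4, 2L * (1:4)), 4, 2,
#'             dimnames = list(paste0("g", 1:4), c("a", "b")))
#' computeSizeFactors(m)
#' @export
computeSizeFactors <- function(counts, allowPseudoReference = FALSE) {
    counts <- splitCountsInput(counts)$counts
    logc <- log(counts)
    logGeo <- rowMeans(logc)
    usable <- is.finite(logGeo)
    if (!any(usable)) {
        if (!allowPseudoReference)
            stop("no gene has positive counts in every sample; rerun with ",
                 "allowPseudoReference = TRUE to use a pseudo-reference ",
                 "over positive entries only")
        logGeo <- apply(logc, 1, function(r) {
            r <- r[is.finite(r)]
            if (length(r)) mean(r) else -Inf
        })
        usable <- is.finite(logGeo)
        if (!any(usable))
            stop("all counts are zero; size factors undefined")
    }
    sf <- apply(counts, 2, function(col) {
        ratios <- log(col[usable]) - logGeo[usable]
        ratios <- ratios[is.finite(ratios)]
        if (!length(ratios))
            stop("a sample shares no positive gene with the reference")
        exp(stats::median(ratios))
    })
    stats::setNames(sf, colnames(counts))
}

#' Variance-stabilising transform (log2 of normalised counts)
#'
#' A deliberately simple, strictly monotone stand-in for a full
#' mean-dispersion-calibrated VST: `log2(count / sizeFactor + 1)` per
#' cell. Adequate for PCA and clustering of simulated bulk libraries.
#'
#' @param counts gene x sample count matrix (or `SummarizedExperiment`).
#' @param sizeFactors positive per-sample factors; computed with
#'   [computeSizeFactors()] when omitted.
#' @return numeric matrix of transformed values, same dimnames.
#' @export
vstTransform <- function(counts, sizeFactors = NULL) {
    counts <- splitCountsInput(counts)$counts
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts)
    if (any(sizeFactors <= 0))
        stop("size factors must be positive")
    log2(sweep(counts, 2, sizeFactors, "/") + 1)
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments estimation under the NB variance function
#' `var = mu + alpha * mu^2`: within each condition group with >= 2
#' replicates, `alpha_hat = (s^2 - m) / m^2` on size-factor-normalised
#' counts, pooled across groups with weights `n_k - 1` and floored at 0;
#' gene-wise estimates are then shrunk 50/50 toward a fitted parametric
#' mean-dispersion trend `alpha(m) = a0 + a1 / m`.
#'
#' When no group has replication the gene-wise component is unavailable
#' and a default trend (`a0 = 0.01`, `a1 = 1`) is returned for every gene,
#' with a warning.
#'
#' @param counts gene x sample count matrix (or `SummarizedExperiment`).
#' @param groups factor of condition membership per sample (interaction of
#'   the design factors).
#' @param sizeFactors optional per-sample factors.
#' @return named numeric vector of per-gene dispersions (>= 0).
#' @export
estimateDispersion <- function(counts, groups, sizeFactors = NULL) {
    counts <- splitCountsInput(counts)$counts
    groups <- as.factor(groups)
    if (length(groups) != ncol(counts))
        stop("groups must have one entry per sample")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts)
    norm <- sweep(counts, 2, sizeFactors, "/")
    baseMean <- rowMeans(norm)

    reps <- table(groups)
    usable <- names(reps)[reps >= 2]
    if (!length(usable)) {
        warning("no condition group has >= 2 replicates; ",
                "returning trend-only dispersions (a0 = 0.01, a1 = 1)")
        alpha <- 0.01 + 1 / pmax(baseMean, 1e-8)
        return(stats::setNames(pmin(alpha, 10), rownames(counts)))
    }

    num <- rep(0, nrow(counts))
    den <- rep(0, nrow(counts))
    for (g in usable) {
        sub <- norm[, groups == g, drop = FALSE]
        n <- ncol(sub)
        m <- rowMeans(sub)
        v <- apply(sub, 1, stats::var)
        ok <- m > 0
        contrib <- ifelse(ok, (v - m) / m^2, 0)
        num <- num + (n - 1) * ifelse(ok, contrib, 0)
        den <- den + (n - 1) * as.numeric(ok)
    }
    genewise <- pmax(0, ifelse(den > 0, num / pmax(den, 1), 0))

    # parametric trend alpha(m) = a0 + a1/m fit on informative genes
    fitOk <- baseMean > 0 & den > 0
    a0 <- 0.01; a1 <- 1
    if (sum(fitOk) >= 10 && stats::sd(baseMean[fitOk]) > 1e-8) {
        fit <- stats::lm(genewise[fitOk] ~ I(1 / baseMean[fitOk]))
        cf <- stats::coef(fit)
        if (all(is.finite(cf))) {
            a0 <- max(cf[1], 1e-8)
            a1 <- max(cf[2], 0)
        }
    } else if (sum(fitOk) > 0) {
        # flat mean profile: the trend collapses to the average estimate
        a0 <- max(mean(genewise[fitOk]), 1e-8)
        a1 <- 0
    }
    trend <- a0 + a1 / pmax(baseMean, 1e-8)
    alpha <- 0.5 * genewise + 0.5 * trend
    stats::setNames(pmin(pmax(alpha, 0), 10), rownames(counts))
}

# IRLS fit of an NB log-link GLM with fixed dispersion; returns the
# coefficient vector and its covariance (ridge-stabilised (X'WX)^-1)
nbIRLS <- function(y, X, offset, alpha) {
    # working init on shifted log counts
    z0 <- log(y + 0.5) - offset
    beta <- tryCatch(qr.solve(X, z0), error = function(e) rep(0, ncol(X)))
    for (it in seq_len(50)) {
        eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
        mu <- exp(eta)
        w <- mu / (1 + alpha * mu)
        z <- (eta - offset) + (y - mu) / mu
        XtW <- t(X * w)
        A <- XtW %*% X + diag(1e-8, ncol(X))
        betaNew <- drop(solve(A, XtW %*% z))
        if (max(abs(betaNew - beta)) < 1e-8) {
            beta <- betaNew
            break
        }
        beta <- betaNew
    }
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    A <- t(X * w) %*% X + diag(1e-8, ncol(X))
    list(beta = beta, cov = solve(A))
}

#' Negative-binomial Wald test for a two-level contrast
#'
#' Fits, per gene, a negative-binomial log-link regression of counts on
#' the contrast factor (plus optional covariate factors), with
#' `log(sizeFactor)` offsets and fixed gene-wise dispersions from
#' [estimateDispersion()]. The contrast coefficient (level A vs level B,
#' natural log) is converted to a log2 fold-change, and a two-sided Wald
#' test with Benjamini-Hochberg adjustment yields the significance call at
#' `padj < alpha`. Genes with all-zero counts across the contrast samples
#' get `NA` p-values and are excluded from the BH family.
#'
#' @param counts gene x sample count matrix or `SummarizedExperiment`
#'   with a `counts` assay and the design factors in `colData`.
#' @param metadata per-sample data.frame (ignored when `counts` is a
#'   `SummarizedExperiment`).
#' @param contrast character(3): factor name, numerator level A,
#'   denominator level B; positive log2FC means higher in A.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param covariates additional metadata factor names adjusted for in the
#'   design (e.g. `"stage"`).
#' @param dispersions,sizeFactors optional precomputed values.
#' @return a \linkS4class{DEResult} with one row per gene.
#' @examples
#' sim <- makeCounts(designSpec(nGenes = 50), seed = 1)
#' germ <- sim[, sim$cell_type == "germ" & sim$stage != "early"]
#' res <- waldDE(germ, contrast = c("genotype", "hpo_RNAi", "control"))
#' head(as.data.frame(res))
#' @export
waldDE <- function(counts, metadata = NULL,
                   contrast = c("genotype", "hpo_RNAi", "control"),
                   alpha = 0.05, covariates = character(),
                   dispersions = NULL, sizeFactors = NULL) {
    inp <- splitCountsInput(counts, metadata)
    counts <- inp$counts; meta <- inp$meta
    if (length(contrast) != 3)
        stop("contrast must be c(factor, levelA, levelB)")
    fac <- contrast[1]; lvlA <- contrast[2]; lvlB <- contrast[3]
    if (!fac %in% colnames(meta))
        stop("contrast factor '", fac, "' not in metadata")
    keep <- meta[[fac]] %in% c(lvlA, lvlB)
    if (!any(meta[[fac]] == lvlA) || !any(meta[[fac]] == lvlB))
        stop("both contrast levels must be present in the metadata")
    counts <- counts[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    grp <- stats::relevel(factor(meta[[fac]], levels = c(lvlB, lvlA)),
                          ref = lvlB)

    form <- if (length(covariates))
        stats::as.formula(paste("~", paste(c(covariates, ".grp."),
                                           collapse = " + ")))
    else stats::as.formula("~ .grp.")
    mf <- cbind(meta, .grp. = grp)
    X <- stats::model.matrix(form, data = mf)
    if (qr(X)$rank < ncol(X))
        stop("design matrix not full rank; factors {",
             paste(c(covariates, fac), collapse = ", "),
             "} are confounded")
    coefName <- paste0(".grp.", lvlA)

    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts)
    sizeFactors <- sizeFactors[colnames(counts)]
    offset <- log(sizeFactors)
    if (is.null(dispersions)) {
        gfac <- interaction(meta[, c(covariates, fac), drop = FALSE],
                            drop = TRUE)
        dispersions <- estimateDispersion(counts, gfac, sizeFactors)
    }
    dispersions <- dispersions[rownames(counts)]

    n <- nrow(counts)
    lfc <- se <- rep(NA_real_, n)
    baseMean <- rowMeans(sweep(counts, 2, sizeFactors, "/"))
    nonzero <- rowSums(counts) > 0
    for (i in which(nonzero)) {
        fit <- nbIRLS(counts[i, ], X, offset, dispersions[i])
        k <- match(coefName, colnames(X))
        lfc[i] <- fit$beta[k] / log(2)
        se[i] <- sqrt(fit$cov[k, k]) / log(2)
    }
    stat <- lfc / se
    pvalue <- 2 * stats::pnorm(-abs(stat))
    padj <- bhAdjust(pvalue)
    significant <- !is.na(padj) & padj < alpha

    res <- S4Vectors::DataFrame(
        baseMean = baseMean, log2FC = lfc, SE = se, stat = stat,
        pvalue = pvalue, padj = padj, significant = significant,
        row.names = rownames(counts))
    out <- methods::new("DEResult", res)
    metadata(out) <- list(contrast = contrast, alpha = alpha,
                          covariates = covariates)
    out
}

#' Benjamini-Hochberg adjustment with NA handling
#'
#' Step-up BH false-discovery-rate adjustment. `NA` entries (untested
#' genes) are excluded from the family size `m` and stay `NA`; values are
#' capped at 1. Inputs outside \[0, 1\] are a validation error.
#'
#' @param p numeric vector of p-values (NAs allowed).
#' @return numeric vector of adjusted p-values, same length and names.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    names(out) <- names(p)
    out
}

#' Flag anomalous control samples by marker expression
#'
#' Encodes, as a reproducible rule, the removal of a control library whose
#' marker-gene expression is anomalously low relative to its peers: within
#' each cell type, a control sample is flagged when its marker expression
#' on the variance-stabilised scale (`log2(count / sizeFactor + 1)`, the
#' same scale on which such outliers are inspected visually) deviates
#' from the median of all control samples of that cell type (across
#' stages) by more than `k` scaled median absolute deviations. Cell types
#' with fewer than 3 control samples cannot be assessed and produce a
#' warning.
#'
#' @param counts gene x sample count matrix or `SummarizedExperiment`.
#' @param metadata per-sample data.frame with `cell_type` and `genotype`.
#' @param marker marker gene ID (e.g. `"yki"`).
#' @param k MAD multiplier (default 3); `Inf` flags nothing.
#' @param sizeFactors optional per-sample factors.
#' @return character vector of flagged sample IDs (possibly empty).
#' @export
flagOutlierControls <- function(counts, metadata = NULL, marker,
                                k = 3, sizeFactors = NULL) {
    inp <- splitCountsInput(counts, metadata)
    counts <- inp$counts; meta <- inp$meta
    if (!marker %in% rownames(counts))
        stop("marker gene '", marker, "' not in counts")
    if (!all(c("cell_type", "genotype") %in% colnames(meta)))
        stop("metadata needs cell_type and genotype columns")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts)
    expr <- log2(counts[marker, ] / sizeFactors + 1)

    flagged <- character()
    for (ct in unique(meta$cell_type)) {
        idx <- which(meta$cell_type == ct & meta$genotype == "control")
        if (length(idx) < 3) {
            warning("fewer than 3 control samples for cell type '", ct,
                    "'; outlier flagging skipped")
            next
        }
        x <- expr[idx]
        med <- stats::median(x)
        madv <- stats::mad(x)
        if (!is.finite(k)) next
        dev <- abs(x - med)
        hit <- if (madv > 0) dev > k * madv else dev > 0
        flagged <- c(flagged, colnames(counts)[idx][hit])
    }
    flagged
}
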