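#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn RegenExperiment-class the raw count matrix.
#' @param object a `RegenExperiment`.
#' @export
setMethod("counts", "RegenExperiment", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname pairIds
#' @export
setMethod("pairIds", "RegenExperiment", function(x)
    unique(SummarizedExperiment::colData(x)$pairId))

.sizeFactorsMatrix <- function(cts) {
    logGeo <- rowMeans(log(cts))
    use <- is.finite(logGeo)
    if (!any(use))
        stop("cannot normalize: no gene has nonzero counts in every sample; ",
             "the median-of-ratios reference is undefined")
    apply(cts, 2L, function(col)
        stats::median(exp(log(col[use]) - logGeo[use])))
}

#' Median-of-ratios size factors
#'
#' Estimates one positive scale factor per sample as the median, over genes
#' with nonzero counts in every sample, of that sample's counts divided by
#' the gene's geometric mean across samples. Dividing counts by these
#' factors yields normalized counts comparable across libraries.
#'
#' @param object a [RegenExperiment-class] or a count matrix.
#' @param ... ignored.
#' @return Named numeric vector of per-sample size factors.
#' @examples
#' m <- cbind(a = c(10, 30, 50), b = c(20, 60, 100))
#' rownames(m) <- paste0("g", 1:3)
#' estimateSizeFactors(m)   # sqrt(1/2), sqrt(2)
#' @export
setMethod("estimateSizeFactors", "RegenExperiment", function(object, ...)
    .sizeFactorsMatrix(counts(object)))

#' @rdname estimateSizeFactors-RegenExperiment-method
#' @export
setMethod("estimateSizeFactors", "matrix", function(object, ...)
    .sizeFactorsMatrix(object))

.pairColumns <- function(object, pairId) {
    cd <- SummarizedExperiment::colData(object)
    sel <- which(cd$pairId == pairId)
    if (!length(sel))
        stop("pair '", pairId, "' not present in the sample sheet")
    split(sel, factor(cd$condition[sel], levels = c("wt", "mut")))
}

#' Gene-wise method-of-moments dispersion
#'
#' For one contrast, estimates the NB dispersion of each gene as
#' `max(floor, (s2 - m) / m^2)` from normalized counts, where `m` is the
#' gene's mean over the contrast's samples and `s2` its within-condition
#' pooled sample variance (wildtype and mutant variances pooled by degrees
#' of freedom, so planted fold changes do not inflate the estimate). No
#' shrinkage is applied; the floor (default `1e-8`) keeps downstream Wald
#' statistics defined when the moment estimate is non-positive.
#'
#' @param object a [RegenExperiment-class].
#' @param pairId contrast to use.
#' @param sizeFactors optional precomputed size factors (all samples).
#' @param floor lower bound on the estimate.
#' @param ... ignored.
#' @return Named per-gene dispersion vector.
#' @export
setMethod("estimateDispersions", "RegenExperiment",
    function(object, pairId, sizeFactors = NULL, floor = 1e-8, ...) {
    if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(object)
    cols <- .pairColumns(object, pairId)
    q <- sweep(counts(object), 2L, sizeFactors, "/")
    qwt <- q[, cols$wt, drop = FALSE]
    qmut <- q[, cols$mut, drop = FALSE]
    ss <- rowSums((qwt - rowMeans(qwt))^2) + rowSums((qmut - rowMeans(qmut))^2)
    s2 <- ss / (length(cols$wt) + length(cols$mut) - 2L)
    m <- rowMeans(q[, c(cols$wt, cols$mut), drop = FALSE])
    alpha <- ifelse(m > 0, (s2 - m) / m^2, floor)
    stats::setNames(pmax(floor, alpha), rownames(object))
})

#' Negative-binomial Wald test for one contrast
#'
#' Tests mutant-vs-wildtype differential expression gene by gene. The log2
#' fold change is computed from normalized condition means with a
#' pseudocount; its standard error comes from the NB variance
#' `mu + alpha * mu^2` by the delta method; the Wald statistic is referred
#' to the standard normal two-sidedly, and p-values are Benjamini-Hochberg
#' adjusted across the contrast's tested genes. Genes with all-zero counts
#' in both conditions are untestable and reported with `NA` statistics.
#'
#' @param object a [RegenExperiment-class].
#' @param pairId contrast to test.
#' @param sizeFactors optional precomputed size factors.
#' @param dispersions optional per-gene dispersions for this contrast.
#' @param pseudocount added to each normalized condition mean before the
#'   log-ratio (default 0.5).
#' @return A [ContrastTable-class] with one row per gene.
#' @examples
#' re <- simulateCounts(SimConfig(nGenes = 300, seed = 3L))
#' tab <- waldDETest(re, "S1")
#' head(tab[order(tab$pvalue), ])
#' @export
waldDETest <- function(object, pairId, sizeFactors = NULL,
                       dispersions = NULL, pseudocount = 0.5) {
    stopifnot(is(object, "RegenExperiment"))
    if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(object)
    if (is.null(dispersions))
        dispersions <- estimateDispersions(object, pairId,
                                           sizeFactors = sizeFactors)
    cols <- .pairColumns(object, pairId)
    cts <- counts(object)
    sfWt <- sizeFactors[cols$wt]
    sfMut <- sizeFactors[cols$mut]
    qWt <- sweep(cts[, cols$wt, drop = FALSE], 2L, sfWt, "/")
    qMut <- sweep(cts[, cols$mut, drop = FALSE], 2L, sfMut, "/")
    mWt <- rowMeans(qWt)
    mMut <- rowMeans(qMut)
    baseMean <- (mWt * length(sfWt) + mMut * length(sfMut)) /
        (length(sfWt) + length(sfMut))

    tested <- mWt > 0 | mMut > 0
    log2fc <- log2((mMut + pseudocount) / (mWt + pseudocount))

    # Var(mean of K_j / s_j) with Var(K_j) = mu_j + alpha mu_j^2, mu_j = s_j m
    varMean <- function(m, sf, alpha)
        (m * sum(1 / sf) + alpha * m^2 * length(sf)) / length(sf)^2
    vWt <- varMean(mWt, sfWt, dispersions)
    vMut <- varMean(mMut, sfMut, dispersions)
    ln2sq <- log(2)^2
    se <- sqrt(vWt / ((mWt + pseudocount)^2 * ln2sq) +
               vMut / ((mMut + pseudocount)^2 * ln2sq))
    stat <- log2fc / se
    p <- 2 * stats::pnorm(-abs(stat))

    log2fc[!tested] <- NA_real_
    se[!tested] <- NA_real_
    stat[!tested] <- NA_real_
    p[!tested] <- NA_real_
    fdr <- rep(NA_real_, length(p))
    fdr[tested] <- bhAdjust(p[tested])

    df <- DataFrame(baseMean = unname(baseMean),
                    log2FoldChange = unname(log2fc), lfcSE = unname(se),
                    stat = unname(stat), pvalue = unname(p),
                    fdr = unname(fdr), row.names = rownames(cts))
    new("ContrastTable", df, pairId = pairId)
}

#' @rdname pairId
#' @export
setMethod("pairId", "ContrastTable", function(x) x@pairId)

#' Run the Wald test on every contrast of the panel
#'
#' Convenience wrapper: size factors are estimated once across all samples
#' (as for a single sequencing batch), dispersions and tests per contrast.
#'
#' @param object a [RegenExperiment-class].
#' @param sizeFactors optional precomputed size factors.
#' @param pseudocount see [waldDETest()].
#' @return Named list of [ContrastTable-class], one per pair id.
#' @export
runContrasts <- function(object, sizeFactors = NULL, pseudocount = 0.5) {
    if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(object)
    ids <- pairIds(object)
    stats::setNames(lapply(ids, function(p)
        waldDETest(object, p, sizeFactors = sizeFactors,
                   pseudocount = pseudocount)), ids)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with tail monotonization, as used for every FDR column in the
#' package. Input values outside `[0, 1]` are rejected; `NA`s propagate.
#'
#' @param p numeric vector of p-values.
#' @return Vector of BH-adjusted values (FDR), same order as `p`.
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p))
        stop("p must be numeric")
    bad <- !is.na(p) & (p < 0 | p > 1)
    if (any(bad))
        stop("p-values outside [0, 1] at positions: ",
             paste(utils::head(which(bad), 5L), collapse = ", "))
    stats::p.adjust(p, method = "BH")
}
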