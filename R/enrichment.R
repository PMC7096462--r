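#' @include AllClasses.R de.R
NULL

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditional on both margins, sums hypergeometric probabilities of all
#' tables at most as probable as the observed one (with the conventional
#' `1 + 1e-7` relative tolerance on the comparison). Cells follow the ORA
#' layout: `a` = foreground genes in the set, `b` = foreground outside,
#' `c` = set members outside the foreground, `d` = the rest.
#'
#' @param a,b,c,d non-negative integer cells.
#' @return p-value in (0, 1].
#' @export
fisherExactP <- function(a, b, c, d) {
    stopifnot(min(a, b, c, d) >= 0)
    K <- a + c                     # set size
    n <- a + b                     # foreground size
    N <- a + b + c + d
    support <- max(0L, n + K - N):min(n, K)
    probs <- stats::dhyper(support, K, N - K, n)
    pObs <- probs[match(a, support)]
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

.oddsRatio <- function(a, b, c, d) {
    if (min(a, b, c, d) == 0) {
        a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    (a * d) / (b * c)
}

#' Fisher over-representation of a gene list in a catalog
#'
#' Tests each catalog set for overlap with `associated` within the catalog
#' universe, after removing sets outside the `[minSet, maxSet]` size window
#' (sizes measured after intersection with the universe). Removed sets are
#' retained as rows with `NA` statistics and a `failingFilter` reason. The
#' odds ratio is the cross-product `ad/bc` with a 0.5 Haldane-Anscombe
#' adjustment to all cells only when some cell is zero; the p-value always
#' uses the unmodified table. FDR is Benjamini-Hochberg across tested sets.
#'
#' @param associated character vector of foreground genes (must lie in the
#'   universe); an empty foreground yields p = 1 for every set and a
#'   `flag` note in `metadata()`.
#' @param catalog a [GeneSetCatalog-class].
#' @param minSet,maxSet set-size filters (defaults 10 and 500).
#' @return A [S4Vectors::DataFrame]: `set`, `setSize`, `a`, `b`, `c`, `d`,
#'   `oddsRatio`, `pvalue`, `fdr`, `failingFilter`.
#' @examples
#' cat <- GeneSetCatalog(list(s1 = letters[1:12]), universe = letters)
#' fisherORA(letters[1:5], cat, minSet = 2)
#' @export
fisherORA <- function(associated, catalog, minSet = 10L, maxSet = 500L) {
    stopifnot(is(catalog, "GeneSetCatalog"))
    uni <- catalog@universe
    if (!length(uni)) stop("empty universe")
    associated <- unique(as.character(associated))
    if (!all(associated %in% uni))
        stop("associated genes outside the universe: ",
             paste(utils::head(setdiff(associated, uni), 5L), collapse = ", "))
    sets <- catalog@sets
    sizes <- lengths(sets)
    filt <- rep(NA_character_, length(sets))
    filt[sizes < minSet] <- "set_too_small"
    filt[sizes > maxSet] <- "set_too_large"

    nA <- length(associated)
    N <- length(uni)
    nS <- length(sets)
    aV <- bV <- cV <- dV <- rep(NA_integer_, nS)
    orV <- pV <- fdrV <- rep(NA_real_, nS)
    keep <- is.na(filt)
    for (i in which(keep)) {
        a <- sum(sets[[i]] %in% associated)
        aV[i] <- a
        bV[i] <- nA - a
        cV[i] <- sizes[[i]] - a
        dV[i] <- N - aV[i] - bV[i] - cV[i]
        orV[i] <- .oddsRatio(aV[i], bV[i], cV[i], dV[i])
        pV[i] <- fisherExactP(aV[i], bV[i], cV[i], dV[i])
    }
    fdrV[keep] <- bhAdjust(pV[keep])
    res <- DataFrame(set = names(sets), setSize = unname(sizes),
                     a = aV, b = bV, c = cV, d = dV, oddsRatio = orV,
                     pvalue = pV, fdr = fdrV, failingFilter = filt)
    if (nA == 0L)
        metadata(res)$flag <- "empty foreground: all p-values are 1"
    res
}

#' Per-contrast over-representation of DE genes
#'
#' For every contrast, takes its differentially expressed genes
#' (`fdr < deFdr`, either direction) as foreground and runs [fisherORA()]
#' against the catalog; results are stacked with a `pairId` column.
#'
#' @param contrasts named list of [ContrastTable-class].
#' @param catalog a [GeneSetCatalog-class]; its universe should be the genes
#'   tested in all contrasts (see [testedUniverse()]).
#' @param deFdr DE significance cutoff (default 0.05, strict `<`).
#' @param minSet,maxSet passed to [fisherORA()].
#' @return A [S4Vectors::DataFrame], one row per (set, pair).
#' @export
perPairSetTest <- function(contrasts, catalog, deFdr = 0.05,
                           minSet = 10L, maxSet = 500L) {
    out <- lapply(names(contrasts), function(p) {
        tab <- contrasts[[p]]
        de <- rownames(tab)[!is.na(tab$fdr) & tab$fdr < deFdr]
        de <- intersect(de, catalog@universe)
        r <- fisherORA(de, catalog, minSet = minSet, maxSet = maxSet)
        r$pairId <- p
        r
    })
    do.call(rbind, out)
}

#' Genes tested in every contrast
#'
#' The enrichment universe: genes with a defined p-value in all supplied
#' contrast tables.
#'
#' @param contrasts named list of [ContrastTable-class].
#' @return Character vector of gene ids.
#' @export
testedUniverse <- function(contrasts) {
    p <- .contrastMatrix(contrasts, names(contrasts), "pvalue")
    rownames(p)[rowSums(is.na(p)) == 0L]
}

#' Label gene sets enriched specifically in regeneration contrasts
#'
#' A set is labeled enriched when (i) in at least one regeneration contrast
#' its odds ratio exceeds 1 and the significance condition holds, (ii) every
#' non-regeneration contrast is less significant - its p-value strictly
#' exceeds the smallest p among the qualifying regeneration contrasts -
#' (iii) it passed the size filters, and (iv) it contains at least
#' `minAssoc` regeneration-associated genes.
#'
#' The published significance clause reads "odds ratio > 1 and (FDR > 0.1 or
#' P-value > 0.01)"; taken literally that selects *non*-significant sets,
#' which cannot yield an enriched label. `reading = "significance"`
#' (default) inverts the inequalities (`fdr < sigFdr` or `p < sigP`);
#' `reading = "literal"` applies them as printed. With `"literal"` the
#' less-significant clause falls back to the same strict p ordering.
#'
#' @param perPair output of [perPairSetTest()] covering every panel pair.
#' @param associated character vector of regeneration-associated genes (for
#'   the `minAssoc` membership filter).
#' @param catalog the [GeneSetCatalog-class] tested.
#' @param panel a [ContrastPanel-class].
#' @param config an [EnrichmentConfig-class].
#' @param reading `"significance"` (default) or `"literal"`.
#' @return A [S4Vectors::DataFrame]: `set`, `enriched`, `qualifyingPairs`
#'   (comma-separated), `minRegenP`, `assocCount`, `failingFilter`.
#' @export
labelEnrichedSets <- function(perPair, associated, catalog,
                              panel = ContrastPanel(),
                              config = EnrichmentConfig(),
                              reading = c("significance", "literal")) {
    reading <- match.arg(reading)
    validObject(panel); validObject(config)
    allPairs <- c(panel@regenPairs, panel@nonregenPairs)
    missing <- setdiff(allPairs, unique(perPair$pairId))
    if (length(missing))
        stop("per-pair results missing for: ", paste(missing, collapse = ", "))
    setNames <- unique(perPair$set)
    assocCount <- vapply(catalog@sets[setNames], function(s)
        sum(s %in% associated), integer(1))

    getCol <- function(col) {
        m <- matrix(NA_real_, length(setNames), length(allPairs),
                    dimnames = list(setNames, allPairs))
        sel <- perPair$pairId %in% allPairs
        m[cbind(match(perPair$set[sel], setNames),
                match(perPair$pairId[sel], allPairs))] <- perPair[[col]][sel]
        m
    }
    orM <- getCol("oddsRatio")
    pM <- getCol("pvalue")
    fM <- getCol("fdr")
    sizes <- perPair$setSize[match(setNames, perPair$set)]
    sizeFail <- perPair$failingFilter[match(setNames, perPair$set)]
    sizeFail[is.na(sizeFail) & sizes < config@minSet] <- "set_too_small"
    sizeFail[is.na(sizeFail) & sizes > config@maxSet] <- "set_too_large"

    enriched <- logical(length(setNames))
    qual <- character(length(setNames))
    minP <- rep(NA_real_, length(setNames))
    failing <- sizeFail
    for (i in seq_along(setNames)) {
        if (!is.na(sizeFail[i])) next
        if (assocCount[i] < config@minAssoc) {
            failing[i] <- "too_few_associated_members"
            next
        }
        sig <- if (reading == "significance")
            fM[i, panel@regenPairs] < config@sigFdr |
                pM[i, panel@regenPairs] < config@sigP
        else
            fM[i, panel@regenPairs] > config@sigFdr |
                pM[i, panel@regenPairs] > config@sigP
        ok <- orM[i, panel@regenPairs] > 1 & sig
        ok[is.na(ok)] <- FALSE
        if (!any(ok)) next
        qp <- panel@regenPairs[ok]
        minP[i] <- min(pM[i, qp])
        if (all(pM[i, panel@nonregenPairs] > minP[i])) {
            enriched[i] <- TRUE
            qual[i] <- paste(qp, collapse = ",")
        }
    }
    DataFrame(set = setNames, enriched = enriched, qualifyingPairs = qual,
              minRegenP = minP, assocCount = unname(assocCount),
              failingFilter = failing)
}
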