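#' @include AllClasses.R de.R
NULL

.contrastMatrix <- function(contrasts, pairs, column) {
    genes <- rownames(contrasts[[pairs[1L]]])
    m <- vapply(pairs, function(p) {
        tab <- contrasts[[p]]
        if (is.null(tab)) stop("missing contrast table for pair '", p, "'")
        if (!identical(rownames(tab), genes))
            stop("contrast tables disagree on gene ids/order")
        tab[[column]]
    }, numeric(length(genes)))
    if (is.null(dim(m)))
        m <- matrix(m, nrow = 1L, dimnames = list(NULL, pairs))
    rownames(m) <- genes
    m
}

#' Cross-contrast signature classification
#'
#' Labels each gene, for each regeneration contrast X, as `X-up` when it is
#' significantly up-regulated in X (`fdr < fdrSig` and `log2FC > 0`), not
#' significant in any non-regeneration contrast (`p >= pNonsig` and
#' `fdr >= fdrNonsig` in all of them), and every non-regeneration log2 fold
#' change lies at least `marginLog2` below X's; `X-down` mirrors the signs.
#' Genes lacking a defined test in any contrast of the panel are untestable
#' and labeled `none` throughout.
#'
#' The published down-gene margin is stated as "log2 fold change not greater
#' than log2(FC of X) + 0.2", which read literally tolerates arbitrarily
#' strong down-regulation in the control contrasts; `margin = "mirrored"`
#' (default) instead requires each control log2FC to sit at least
#' `marginLog2` above X's, enforcing specificity symmetrically.
#' `margin = "literal"` applies the printed inequality as written.
#'
#' @param contrasts named list of [ContrastTable-class], one per panel pair.
#' @param panel a [ContrastPanel-class].
#' @param thresholds a [SignatureThresholds-class].
#' @param margin `"mirrored"` (default) or `"literal"` down-gene margin.
#' @return A [S4Vectors::DataFrame] with rownames = genes, one
#'   factor-like character column per regeneration pair
#'   (`"up"`/`"down"`/`"none"`) and a logical `testable` column. The panel,
#'   thresholds and margin reading are echoed in `metadata()`.
#' @examples
#' re <- simulateCounts(SimConfig(nGenes = 400, seed = 11L))
#' calls <- classifyGenes(runContrasts(re))
#' table(calls$S1)
#' @export
classifyGenes <- function(contrasts, panel = ContrastPanel(),
                          thresholds = SignatureThresholds(),
                          margin = c("mirrored", "literal")) {
    margin <- match.arg(margin)
    validObject(panel); validObject(thresholds)
    allPairs <- c(panel@regenPairs, panel@nonregenPairs)
    if (!all(allPairs %in% names(contrasts)))
        stop("contrasts missing for: ",
             paste(setdiff(allPairs, names(contrasts)), collapse = ", "))
    lfc <- .contrastMatrix(contrasts, allPairs, "log2FoldChange")
    pm <- .contrastMatrix(contrasts, allPairs, "pvalue")
    fm <- .contrastMatrix(contrasts, allPairs, "fdr")
    genes <- rownames(lfc)
    nr <- panel@nonregenPairs

    testable <- rowSums(is.na(lfc) | is.na(pm) | is.na(fm)) == 0L
    nonsigAll <- rowSums(pm[, nr, drop = FALSE] >= thresholds@pNonsig &
                         fm[, nr, drop = FALSE] >= thresholds@fdrNonsig) ==
        length(nr)

    out <- DataFrame(row.names = genes)
    for (X in panel@regenPairs) {
        marginUp <- rowSums(lfc[, nr, drop = FALSE] <=
                            lfc[, X] - thresholds@marginLog2) == length(nr)
        marginDown <- if (margin == "mirrored")
            rowSums(lfc[, nr, drop = FALSE] >=
                    lfc[, X] + thresholds@marginLog2) == length(nr)
        else
            rowSums(lfc[, nr, drop = FALSE] <=
                    lfc[, X] + thresholds@marginLog2) == length(nr)
        up <- lfc[, X] > 0 & fm[, X] < thresholds@fdrSig & nonsigAll & marginUp
        down <- lfc[, X] < 0 & fm[, X] < thresholds@fdrSig & nonsigAll &
            marginDown
        lab <- rep("none", length(genes))
        lab[up & testable] <- "up"
        lab[down & testable] <- "down"
        out[[X]] <- lab
    }
    out$testable <- as.logical(testable)
    metadata(out) <- list(panel = panel, thresholds = thresholds,
                          margin = margin)
    out
}

#' Aggregate per-contrast labels into regeneration-associated gene lists
#'
#' In `"intersection"` mode (default) a gene is regeneration-associated-up
#' when it is labeled up in every regeneration contrast; `"union"` mode
#' requires any one. Down mirrors up. A gene can never be both (each
#' per-contrast label is single-valued).
#'
#' @param calls output of [classifyGenes()].
#' @param mode `"intersection"` or `"union"`.
#' @return List with character vectors `up` and `down` and the `mode` used.
#' @export
callRegenerationAssociated <- function(calls,
                                       mode = c("intersection", "union")) {
    mode <- match.arg(mode)
    panel <- metadata(calls)$panel
    regen <- if (!is.null(panel)) panel@regenPairs
             else setdiff(colnames(calls), "testable")
    lab <- as.matrix(as.data.frame(calls[, regen, drop = FALSE]))
    agg <- function(dir) {
        hit <- lab == dir
        if (mode == "intersection") rowSums(hit) == ncol(hit)
        else rowSums(hit) > 0L
    }
    list(up = rownames(calls)[agg("up")],
         down = rownames(calls)[agg("down")],
         mode = mode)
}
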