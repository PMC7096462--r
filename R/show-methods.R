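#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname geneSets
#' @export
setMethod("geneSets", "GeneSetCatalog", function(x) x@sets)

#' @rdname geneSets
#' @export
setMethod("universe", "GeneSetCatalog", function(x) x@universe)

#' @rdname geneSets
#' @export
setMethod("plantedSets", "GeneSetCatalog", function(x) x@planted)

setMethod("show", "GeneSetCatalog", function(object) {
    cat("GeneSetCatalog with", length(object@sets), "sets over a universe of",
        length(object@universe), "genes\n")
    sz <- lengths(object@sets)
    if (length(sz))
        cat("  set sizes:", min(sz), "-", max(sz),
            sprintf("(median %g)\n", stats::median(sz)))
    if (length(object@planted))
        cat("  planted enriched sets:", length(object@planted), "\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes x",
        length(object@pairIds), "pairs x",
        2L * object@nReplicates, "samples/pair\n")
    cat("  regeneration pairs:", paste(object@regenPairs, collapse = ", "),
        "\n")
    cat(sprintf(
        "  planted: %d shared-up, %d shared-down, %d specific/pair at |log2FC| = %g\n",
        object@nSharedUp, object@nSharedDown, object@nSpecificPerPair,
        object@effectLog2FC))
    cat(sprintf("  dispersion %s, seed %d\n",
                paste(signif(unique(object@dispersion), 3), collapse = "/"),
                object@seed))
})

setMethod("show", "ContrastTable", function(object) {
    cat("ContrastTable for pair", object@pairId, "\n")
    callNextMethod()
})

setMethod("show", "LinkageTree", function(object) {
    cat("LinkageTree over", length(object@labels), "contrasts (",
        object@metric, "distance,", object@method, "linkage )\n")
    cat("  merge heights:",
        paste(signif(object@heights, 4), collapse = ", "), "\n")
})

setMethod("show", "ContrastPanel", function(object) {
    cat("ContrastPanel: regeneration =",
        paste(object@regenPairs, collapse = ", "), "| controls =",
        paste(object@nonregenPairs, collapse = ", "), "\n")
})
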