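#' @importFrom BiocGenerics counts estimateSizeFactors estimateDispersions
NULL

#' Planted simulation truth
#'
#' For a simulated [RegenExperiment-class], returns the planted-truth ledger:
#' a [S4Vectors::DataFrame] with one row per gene, the planted `category`
#' (`shared_up`, `shared_down`, `specific:<pair>` or `null`) and one
#' `lfc.<pair>` column of true log2 fold changes per contrast.
#'
#' @param x a simulated `RegenExperiment`.
#' @return A `DataFrame`, or an error for non-simulated objects.
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname simTruth
#' @export
setGeneric("trueLog2FC", function(x) standardGeneric("trueLog2FC"))

#' Accessors for gene-set catalogs
#'
#' `geneSets` returns the named list of sets, `universe` the gene universe,
#' `plantedSets` the names of simulation-planted enriched sets.
#'
#' @param x a [GeneSetCatalog-class].
#' @return list, character vector, character vector respectively.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname geneSets
#' @export
setGeneric("plantedSets", function(x) standardGeneric("plantedSets"))

#' Contrast label of a result table
#' @param x a [ContrastTable-class].
#' @return character scalar.
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' Contrast labels present in an experiment
#' @param x a [RegenExperiment-class].
#' @return character vector in sample-sheet order.
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))
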