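#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Container for a multi-contrast count experiment
#'
#' `RegenExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds an integer gene-by-sample count matrix (assay `"counts"`) together
#' with a sample sheet in `colData` assigning every sample to one
#' wildtype-vs-mutant contrast. Two `colData` columns are required:
#' `pairId` (contrast label, e.g. `"S1"`, `"G3"`) and `condition`
#' (`"wt"` or `"mut"`). Every contrast must carry at least two samples per
#' condition, so that within-condition variances are estimable.
#'
#' Simulated objects additionally carry the planted truth: `rowData(x)$category`
#' and a gene-by-pair matrix of true log2 fold changes in
#' `metadata(x)$trueLog2FC` (see [simulateCounts()] and [simTruth()]).
#'
#' @seealso [RegenExperiment()] for construction from a matrix and sample
#'   sheet, [simulateCounts()] for simulation.
#' @export
setClass("RegenExperiment", contains = "SummarizedExperiment")

.validRegenExperiment <- function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
        else if (any(cts != round(cts)))
            msg <- c(msg, "counts must be integers")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("pairId", "condition")
    if (!all(need %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'pairId' and 'condition'")
    } else {
        if (!all(cd$condition %in% c("wt", "mut")))
            msg <- c(msg, "condition must be 'wt' or 'mut'")
        tab <- table(cd$pairId, cd$condition)
        if (!all(c("wt", "mut") %in% colnames(tab)) || any(tab < 2L))
            msg <- c(msg, "every pairId needs >= 2 samples per condition")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("RegenExperiment", .validRegenExperiment)

#' Construct a RegenExperiment from counts and a sample sheet
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param sampleSheet `data.frame` with columns `sample_id`, `pair_id`,
#'   `condition` (`"wt"`/`"mut"`); rows are matched to `colnames(counts)` by
#'   `sample_id` and may come in any order.
#' @return A [RegenExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(80, 50), nrow = 10,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
#' sheet <- data.frame(sample_id = paste0("s", 1:8),
#'                     pair_id = rep(c("S1", "G2"), each = 4),
#'                     condition = rep(c("wt", "wt", "mut", "mut"), 2))
#' re <- RegenExperiment(cts, sheet)
#' @export
RegenExperiment <- function(counts, sampleSheet) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene rownames and sample colnames")
    need <- c("sample_id", "pair_id", "condition")
    if (!all(need %in% colnames(sampleSheet)))
        stop("sample sheet needs columns: ", paste(need, collapse = ", "))
    missing <- setdiff(colnames(counts), sampleSheet$sample_id)
    orphan <- setdiff(sampleSheet$sample_id, colnames(counts))
    if (length(missing) || length(orphan))
        stop("sample sheet and count matrix disagree on samples: ",
             paste(c(missing, orphan), collapse = ", "))
    idx <- match(colnames(counts), sampleSheet$sample_id)
    cd <- DataFrame(pairId = as.character(sampleSheet$pair_id[idx]),
                    condition = as.character(sampleSheet$condition[idx]),
                    row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("RegenExperiment", se)
}

#' Simulation configuration
#'
#' Describes the planted-truth design of the synthetic seven-contrast
#' experiment: a block of genes up- or down-regulated in every
#' regeneration contrast (default S1, G3, G5) and in none of the others, a
#' block of genes perturbed in exactly one contrast, and a null majority.
#' Baseline means are log-normal; counts are negative binomial with
#' `variance = mu + dispersion * mu^2`; per-sample depth factors are drawn
#' log-uniformly from `libSizeRange`.
#'
#' @slot nGenes total number of genes.
#' @slot nReplicates samples per condition per contrast.
#' @slot pairIds contrast labels, in panel order.
#' @slot regenPairs subset of `pairIds` carrying the shared signature.
#' @slot nSharedUp,nSharedDown genes up/down in all `regenPairs` only.
#' @slot nSpecificPerPair genes perturbed in exactly one contrast (each).
#' @slot effectLog2FC magnitude of every planted log2 fold change (0 gives a
#'   global null).
#' @slot meanLogMu,sdLogMu log-normal baseline mean parameters (natural log).
#' @slot dispersion NB dispersion, scalar or per-gene vector; 0 gives Poisson.
#' @slot libSizeRange range of multiplicative per-sample depth factors.
#' @slot seed integer seed; the simulation is a pure function of the config.
#' @seealso [SimConfig()], [simulateCounts()]
#' @export
setClass("SimConfig",
    representation(nGenes = "integer", nReplicates = "integer",
                   pairIds = "character", regenPairs = "character",
                   nSharedUp = "integer", nSharedDown = "integer",
                   nSpecificPerPair = "integer", effectLog2FC = "numeric",
                   meanLogMu = "numeric", sdLogMu = "numeric",
                   dispersion = "numeric", libSizeRange = "numeric",
                   seed = "integer"))

.validSimConfig <- function(object) {
    msg <- NULL
    planted <- object@nSharedUp + object@nSharedDown +
        object@nSpecificPerPair * length(object@pairIds)
    if (planted > object@nGenes)
        msg <- c(msg, sprintf(
            "infeasible gene budget: %d planted genes > %d total",
            planted, object@nGenes))
    if (!all(object@regenPairs %in% object@pairIds))
        msg <- c(msg, "regenPairs must be a subset of pairIds")
    if (anyDuplicated(object@pairIds))
        msg <- c(msg, "pairIds must be unique")
    if (object@nGenes < 1L || object@nReplicates < 2L)
        msg <- c(msg, "need nGenes >= 1 and nReplicates >= 2")
    if (min(object@nSharedUp, object@nSharedDown, object@nSpecificPerPair) < 0L)
        msg <- c(msg, "planted gene counts must be non-negative")
    if (object@effectLog2FC < 0)
        msg <- c(msg, "effectLog2FC must be >= 0")
    if (any(object@dispersion < 0) ||
        !(length(object@dispersion) %in% c(1L, object@nGenes)))
        msg <- c(msg, "dispersion must be >= 0, scalar or one per gene")
    if (length(object@libSizeRange) != 2L || any(object@libSizeRange <= 0) ||
        diff(object@libSizeRange) < 0)
        msg <- c(msg, "libSizeRange must be an increasing positive pair")
    if (object@sdLogMu < 0) msg <- c(msg, "sdLogMu must be >= 0")
    if (is.null(msg)) TRUE else msg
}
setValidity("SimConfig", .validSimConfig)

#' @param nGenes,nReplicates,pairIds,regenPairs,nSharedUp,nSharedDown,nSpecificPerPair,effectLog2FC,meanLogMu,sdLogMu,dispersion,libSizeRange,seed see slots.
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- SimConfig(nGenes = 500, seed = 1L)
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nGenes = 2000L, nReplicates = 3L,
                      pairIds = c("S1", "G2", "G3", "G4", "G5", "G6", "G7"),
                      regenPairs = c("S1", "G3", "G5"),
                      nSharedUp = 100L, nSharedDown = 100L,
                      nSpecificPerPair = 25L, effectLog2FC = 1.5,
                      meanLogMu = log(100), sdLogMu = 1,
                      dispersion = 0.1, libSizeRange = c(0.5, 2),
                      seed = 1L) {
    new("SimConfig", nGenes = as.integer(nGenes),
        nReplicates = as.integer(nReplicates),
        pairIds = as.character(pairIds),
        regenPairs = as.character(regenPairs),
        nSharedUp = as.integer(nSharedUp),
        nSharedDown = as.integer(nSharedDown),
        nSpecificPerPair = as.integer(nSpecificPerPair),
        effectLog2FC = as.numeric(effectLog2FC),
        meanLogMu = as.numeric(meanLogMu), sdLogMu = as.numeric(sdLogMu),
        dispersion = as.numeric(dispersion),
        libSizeRange = as.numeric(libSizeRange), seed = as.integer(seed))
}

#' Per-contrast differential expression table
#'
#' A [S4Vectors::DataFrame] subclass with one row per gene and columns
#' `baseMean` (mean of normalized counts over the contrast's samples),
#' `log2FoldChange` (mutant vs wildtype), `lfcSE`, `stat` (Wald statistic),
#' `pvalue` and `fdr` (Benjamini-Hochberg across the contrast's tested
#' genes). Genes with all-zero counts in both conditions are kept as rows but
#' carry `NA` statistics. The contrast label is in the `pairId` slot.
#'
#' @slot pairId contrast label.
#' @seealso [waldDETest()]
#' @export
setClass("ContrastTable", contains = "DFrame",
         representation(pairId = "character"))

#' Named gene-set catalog with a fixed universe
#'
#' Stores named gene sets (as produced by GMT files) intersected with a
#' gene universe - for signature work the universe is the set of genes tested
#' in all contrasts. `planted` records which sets a simulation enriched for
#' planted signature genes (empty for real catalogs).
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot universe character vector of gene ids.
#' @slot planted names of simulation-planted enriched sets.
#' @seealso [GeneSetCatalog()], [readGMT()], [simulateGeneSetCatalog()]
#' @export
setClass("GeneSetCatalog",
    representation(sets = "list", universe = "character",
                   planted = "character"))

.validGeneSetCatalog <- function(object) {
    msg <- NULL
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)) ||
        any(!nzchar(names(object@sets))))
        msg <- c(msg, "set names must be unique and non-empty")
    if (anyDuplicated(object@universe))
        msg <- c(msg, "universe ids must be unique")
    if (!all(unlist(object@sets, use.names = FALSE) %in% object@universe))
        msg <- c(msg, "set members must lie in the universe")
    if (!all(object@planted %in% names(object@sets)))
        msg <- c(msg, "planted names must name sets")
    if (is.null(msg)) TRUE else msg
}
setValidity("GeneSetCatalog", .validGeneSetCatalog)

#' @param sets named list of character vectors.
#' @param universe gene universe; set members outside it are dropped
#'   (intersection semantics).
#' @param planted optional names of planted enriched sets.
#' @return A validated `GeneSetCatalog`.
#' @rdname GeneSetCatalog-class
#' @export
GeneSetCatalog <- function(sets, universe, planted = character()) {
    sets <- lapply(sets, function(s) unique(as.character(s)[as.character(s) %in% universe]))
    new("GeneSetCatalog", sets = sets, universe = as.character(universe),
        planted = as.character(planted))
}

#' Contrast panel: regeneration vs non-regeneration pairs
#'
#' Fixes which contrasts carry the candidate regeneration signature
#' (default S1 = smn1, G3 = gemin3, G5 = gemin5) and which serve as
#' specificity controls (default G2, G4, G6, G7 = gemin2/4/6/7).
#'
#' @slot regenPairs,nonregenPairs disjoint, non-empty label vectors.
#' @export
setClass("ContrastPanel",
    representation(regenPairs = "character", nonregenPairs = "character"))

setValidity("ContrastPanel", function(object) {
    msg <- NULL
    if (!length(object@regenPairs) || !length(object@nonregenPairs))
        msg <- c(msg, "both pair groups must be non-empty")
    if (length(intersect(object@regenPairs, object@nonregenPairs)))
        msg <- c(msg, "regen and non-regen pairs must be disjoint")
    if (is.null(msg)) TRUE else msg
})

#' @param regenPairs,nonregenPairs see slots.
#' @return A validated `ContrastPanel`.
#' @rdname ContrastPanel-class
#' @export
ContrastPanel <- function(regenPairs = c("S1", "G3", "G5"),
                          nonregenPairs = c("G2", "G4", "G6", "G7")) {
    new("ContrastPanel", regenPairs = as.character(regenPairs),
        nonregenPairs = as.character(nonregenPairs))
}

#' Thresholds for the cross-contrast signature rule
#'
#' A gene is called X-up (X a regeneration contrast) when it is
#' significantly up-regulated there (`fdr < fdrSig`), not significant in any
#' non-regeneration contrast (`p >= pNonsig` and `fdr >= fdrNonsig`), and
#' every non-regeneration log2 fold change sits at least `marginLog2` below
#' the regeneration one (mirrored for X-down). Defaults are the published
#' thresholds: 0.05 / 0.1 / 0.25 / 0.2.
#'
#' @slot fdrSig significance FDR cutoff (strict `<`).
#' @slot pNonsig,fdrNonsig non-significance cutoffs (both `>=`).
#' @slot marginLog2 specificity margin in log2 units.
#' @export
setClass("SignatureThresholds",
    representation(fdrSig = "numeric", pNonsig = "numeric",
                   fdrNonsig = "numeric", marginLog2 = "numeric"))

setValidity("SignatureThresholds", function(object) {
    msg <- NULL
    vals <- c(object@fdrSig, object@pNonsig, object@fdrNonsig)
    if (any(vals <= 0) || any(vals > 1))
        msg <- c(msg, "fdrSig, pNonsig, fdrNonsig must lie in (0, 1]")
    if (object@fdrSig >= object@fdrNonsig)
        msg <- c(msg, "fdrSig must be < fdrNonsig")
    if (object@marginLog2 < 0)
        msg <- c(msg, "marginLog2 must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @param fdrSig,pNonsig,fdrNonsig,marginLog2 see slots.
#' @return A validated `SignatureThresholds`.
#' @rdname SignatureThresholds-class
#' @export
SignatureThresholds <- function(fdrSig = 0.05, pNonsig = 0.1,
                                fdrNonsig = 0.25, marginLog2 = 0.2) {
    new("SignatureThresholds", fdrSig = fdrSig, pNonsig = pNonsig,
        fdrNonsig = fdrNonsig, marginLog2 = marginLog2)
}

#' Configuration for enriched-gene-set labeling
#'
#' Size and count filters plus the significance cutoffs of the
#' contrast-specific enrichment rule: sets with fewer than `minSet` or more
#' than `maxSet` members, or with fewer than `minAssoc`
#' regeneration-associated members, are removed; a surviving set is labeled
#' enriched when, in at least one regeneration contrast, its odds ratio
#' exceeds 1 and it is significant (`fdr < sigFdr` or `p < sigP`), while
#' every non-regeneration contrast is less significant.
#'
#' @slot sigFdr,sigP significance cutoffs (defaults 0.1 and 0.01).
#' @slot minSet,maxSet set-size window (defaults 10 and 500).
#' @slot minAssoc minimum regeneration-associated members (default 3).
#' @export
setClass("EnrichmentConfig",
    representation(sigFdr = "numeric", sigP = "numeric", minSet = "integer",
                   maxSet = "integer", minAssoc = "integer"))

setValidity("EnrichmentConfig", function(object) {
    msg <- NULL
    if (object@sigFdr <= 0 || object@sigP <= 0)
        msg <- c(msg, "sigFdr and sigP must be positive")
    if (object@minSet >= object@maxSet)
        msg <- c(msg, "minSet must be < maxSet")
    if (object@minSet < 1L || object@minAssoc < 0L)
        msg <- c(msg, "minSet must be >= 1 and minAssoc >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @param sigFdr,sigP,minSet,maxSet,minAssoc see slots.
#' @return A validated `EnrichmentConfig`.
#' @rdname EnrichmentConfig-class
#' @export
EnrichmentConfig <- function(sigFdr = 0.1, sigP = 0.01, minSet = 10L,
                             maxSet = 500L, minAssoc = 3L) {
    new("EnrichmentConfig", sigFdr = sigFdr, sigP = sigP,
        minSet = as.integer(minSet), maxSet = as.integer(maxSet),
        minAssoc = as.integer(minAssoc))
}

#' Agglomerative linkage tree over contrasts
#'
#' Records the merge sequence of hierarchical clustering in the same
#' encoding as [stats::hclust]: row i of `merges` gives the two nodes fused
#' at `heights[i]`, negative entries being leaves and positive entries
#' earlier merges. Leaf labels are the contrast (pair) ids.
#'
#' @slot merges integer matrix, (n-1) x 2.
#' @slot heights non-decreasing merge heights (the linkage values).
#' @slot labels leaf labels.
#' @slot method linkage used; @slot metric distance used.
#' @seealso [clusterContrasts()], [treeToNewick()], [asHclust()]
#' @export
setClass("LinkageTree",
    representation(merges = "matrix", heights = "numeric",
                   labels = "character", method = "character",
                   metric = "character"))

setValidity("LinkageTree", function(object) {
    n <- length(object@labels)
    msg <- NULL
    if (nrow(object@merges) != n - 1L || ncol(object@merges) != 2L)
        msg <- c(msg, "need exactly n-1 merges for n leaves")
    if (length(object@heights) != n - 1L)
        msg <- c(msg, "one height per merge")
    if (any(object@heights < -1e-12))
        msg <- c(msg, "heights must be non-negative")
    if (is.null(msg)) TRUE else msg
})
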