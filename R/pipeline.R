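#' @include AllClasses.R simulate.R de.R classify.R cluster.R enrichment.R io.R
NULL

#' Read and validate a pipeline configuration
#'
#' The configuration is one YAML (or JSON) document with either a `sim`
#' block (synthetic mode, fields of [SimConfig()] plus an optional
#' `catalog` block for [simulateGeneSetCatalog()]) or an `inputs` block
#' (paths `counts`, `sampleSheet`, `gmt`) - never both. Optional blocks
#' `panel`, `thresholds`, `enrichment`, `clustering` and scalars `deFdr`,
#' `aggregation`, `margin`, `reading` override the package defaults.
#'
#' @param path YAML/JSON file.
#' @return Validated config list (class `regenSigConfig`).
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    validatePipelineConfig(cfg)
}

#' @param cfg a config list as from [readPipelineConfig()].
#' @rdname readPipelineConfig
#' @export
validatePipelineConfig <- function(cfg) {
    hasSim <- !is.null(cfg$sim)
    hasReal <- !is.null(cfg$inputs)
    if (hasSim == hasReal)
        stop("config must contain exactly one of 'sim' or 'inputs'")
    if (hasReal) {
        need <- c("counts", "sampleSheet", "gmt")
        miss <- setdiff(need, names(cfg$inputs))
        if (length(miss))
            stop("inputs block missing: ", paste(miss, collapse = ", "))
    }
    structure(cfg, class = "regenSigConfig")
}

.cfgPanel <- function(cfg) {
    if (is.null(cfg$panel)) ContrastPanel()
    else ContrastPanel(cfg$panel$regenPairs, cfg$panel$nonregenPairs)
}

.cfgThresholds <- function(cfg) {
    do.call(SignatureThresholds, cfg$thresholds %||% list())
}

.cfgEnrichment <- function(cfg) {
    do.call(EnrichmentConfig, cfg$enrichment %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline input files
#'
#' Checks the on-disk count matrix, sample sheet and (optionally) GMT file
#' before any computation: duplicated gene ids, negative or non-integer
#' counts, samples present in only one of matrix/sheet, invalid condition
#' labels, empty gene sets. A clean report (zero rows) is required by
#' [runPipeline()] before it proceeds.
#'
#' @param countsPath,sampleSheetPath,gmtPath file paths (`gmtPath` optional).
#' @return data.frame with columns `type` and `detail`, one row per problem.
#' @export
validateInputs <- function(countsPath, sampleSheetPath, gmtPath = NULL) {
    issues <- list()
    add <- function(type, detail)
        issues[[length(issues) + 1L]] <<- data.frame(type = type,
                                                     detail = detail)
    df <- utils::read.delim(countsPath, check.names = FALSE)
    genes <- as.character(df[[1L]])
    dup <- unique(genes[duplicated(genes)])
    for (g in dup) add("duplicate_gene", g)
    cts <- as.matrix(df[, -1L, drop = FALSE])
    badNeg <- which(cts < 0, arr.ind = TRUE)
    for (k in seq_len(nrow(badNeg)))
        add("negative_count", paste0(genes[badNeg[k, 1L]], "/",
                                     colnames(cts)[badNeg[k, 2L]]))
    badInt <- which(cts != round(cts), arr.ind = TRUE)
    for (k in seq_len(nrow(badInt)))
        add("non_integer_count", paste0(genes[badInt[k, 1L]], "/",
                                        colnames(cts)[badInt[k, 2L]]))
    sheet <- utils::read.delim(sampleSheetPath)
    for (s in setdiff(sheet$sample_id, colnames(cts)))
        add("sample_not_in_counts", s)
    for (s in setdiff(colnames(cts), sheet$sample_id))
        add("sample_not_in_sheet", s)
    for (bad in unique(setdiff(sheet$condition, c("wt", "mut"))))
        add("invalid_condition", bad)
    if (!is.null(gmtPath)) {
        cat <- readGMT(gmtPath)
        for (s in names(geneSets(cat))[lengths(geneSets(cat)) == 0L])
            add("empty_gene_set", s)
    }
    if (length(issues)) do.call(rbind, issues)
    else data.frame(type = character(), detail = character())
}

#' Run the full signature pipeline
#'
#' Executes simulate (or load + validate), differential expression,
#' signature classification, contrast clustering and gene-set enrichment,
#' writing every stage's output under `outDir` and a `manifest.json`
#' (config echo, package version, seed, per-file MD5 checksums, timestamps)
#' last. Re-running with the same config and seed reproduces identical
#' checksums for every output.
#'
#' @param cfg a `regenSigConfig` (see [readPipelineConfig()]) or plain list.
#' @param outDir output directory, created if absent.
#' @param seed integer master seed (synthetic mode: the count simulation
#'   uses `seed`, the catalog simulation `seed + 1`).
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(cfg, outDir, seed = 1L) {
    if (!inherits(cfg, "regenSigConfig")) cfg <- validatePipelineConfig(cfg)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seed <- as.integer(seed)
    panel <- .cfgPanel(cfg)
    thresholds <- .cfgThresholds(cfg)
    encfg <- .cfgEnrichment(cfg)
    paths <- character()
    out <- function(f) {
        p <- file.path(outDir, f)
        paths[[f]] <<- p
        p
    }
    t0 <- Sys.time()
    .stageLog <- function(stage) message(sprintf("[regenSig] %s (%.1fs)",
        stage, as.numeric(Sys.time() - t0, units = "secs")))

    if (!is.null(cfg$sim)) {
        simArgs <- cfg$sim
        simArgs$catalog <- NULL
        simArgs$seed <- seed
        simCfg <- do.call(SimConfig, simArgs)
        re <- simulateCounts(simCfg)
        writeCounts(re, out("counts.tsv"), out("sample_sheet.tsv"))
        writeSimTruth(re, out("sim_truth.tsv"))
        catArgs <- cfg$sim$catalog %||% list()
        catArgs$x <- re
        catArgs$seed <- seed + 1L
        catalog <- do.call(simulateGeneSetCatalog, catArgs)
        writeGMT(catalog, out("genesets.gmt"))
        .stageLog("simulate")
    } else {
        report <- validateInputs(cfg$inputs$counts, cfg$inputs$sampleSheet,
                                 cfg$inputs$gmt)
        if (nrow(report))
            stop("input validation failed:\n",
                 paste(report$type, report$detail, sep = ": ",
                       collapse = "\n"))
        re <- readCounts(cfg$inputs$counts, cfg$inputs$sampleSheet)
        catalog <- readGMT(cfg$inputs$gmt)
        .stageLog("load")
    }

    sf <- estimateSizeFactors(re)
    utils::write.table(
        data.frame(sample_id = names(sf), size_factor = sf),
        out("size_factors.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    contrasts <- runContrasts(re, sizeFactors = sf)
    for (p in names(contrasts))
        writeContrastTable(contrasts[[p]],
                           out(sprintf("contrast_%s.tsv", p)))
    .stageLog("de")

    margin <- cfg$margin %||% "mirrored"
    aggregation <- cfg$aggregation %||% "intersection"
    calls <- classifyGenes(contrasts, panel, thresholds, margin = margin)
    assoc <- callRegenerationAssociated(calls, mode = aggregation)
    callsDf <- as.data.frame(calls)
    callsDf <- data.frame(gene = rownames(callsDf), callsDf,
                          regeneration_associated = ifelse(
                              rownames(callsDf) %in% assoc$up, "up",
                              ifelse(rownames(callsDf) %in% assoc$down,
                                     "down", "none")))
    utils::write.table(callsDf, out("signature_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
        fdrSig = thresholds@fdrSig, pNonsig = thresholds@pNonsig,
        fdrNonsig = thresholds@fdrNonsig, marginLog2 = thresholds@marginLog2,
        margin = margin, aggregation = aggregation),
        out("signature_thresholds.json"), auto_unbox = TRUE)
    .stageLog("classify")

    profiles <- buildProfileMatrix(contrasts)
    tree <- clusterContrasts(profiles,
                             metric = cfg$clustering$metric %||% "correlation",
                             linkage = cfg$clustering$linkage %||% "average")
    writeLines(treeToNewick(tree), out("dendrogram.newick"))
    utils::write.table(mergeTable(tree), out("merge_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .stageLog("cluster")

    uni <- testedUniverse(contrasts)
    catalog <- GeneSetCatalog(geneSets(catalog), universe = uni,
                              planted = intersect(plantedSets(catalog),
                                                  names(geneSets(catalog))))
    associated <- intersect(c(assoc$up, assoc$down), uni)
    ora <- fisherORA(associated, catalog,
                     minSet = encfg@minSet, maxSet = encfg@maxSet)
    utils::write.table(as.data.frame(ora), out("ora_associated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    perPair <- perPairSetTest(contrasts, catalog, deFdr = cfg$deFdr %||% 0.05,
                              minSet = encfg@minSet, maxSet = encfg@maxSet)
    utils::write.table(as.data.frame(perPair), out("ora_per_pair.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    labels <- labelEnrichedSets(perPair, associated, catalog, panel, encfg,
                                reading = cfg$reading %||% "significance")
    utils::write.table(as.data.frame(labels), out("enriched_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stageLog("enrich")

    manifest <- list(
        package = "regenSig",
        version = as.character(utils::packageVersion("regenSig")),
        seed = seed,
        config = unclass(cfg),
        started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        checksums = as.list(tools::md5sum(unlist(paths))))
    names(manifest$checksums) <- names(paths)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}
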