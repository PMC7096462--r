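#' @include AllClasses.R
NULL

#' Read and write GMT gene-set files
#'
#' GMT is the tab-separated format used by KEGG/GO/InterPro-style catalogs:
#' one set per line - name, description, then member ids. `readGMT`
#' intersects members with `universe` when one is given, otherwise the union
#' of all members becomes the universe.
#'
#' @param path file path.
#' @param universe optional gene universe.
#' @return `readGMT`: a [GeneSetCatalog-class]; `writeGMT`: `path`,
#'   invisibly.
#' @export
readGMT <- function(path, universe = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
        stop("malformed GMT '", path, "': line ", bad[1L],
             " has fewer than 3 fields")
    sets <- lapply(parts, function(x) unique(x[-(1:2)]))
    names(sets) <- vapply(parts, `[`, character(1), 1L)
    if (is.null(universe))
        universe <- sort(unique(unlist(sets, use.names = FALSE)))
    GeneSetCatalog(sets, universe = universe)
}

#' @param catalog a [GeneSetCatalog-class].
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @rdname readGMT
#' @export
writeGMT <- function(catalog, path, descriptions = NULL) {
    stopifnot(is(catalog, "GeneSetCatalog"))
    nm <- names(catalog@sets)
    if (is.null(descriptions)) descriptions <- nm
    lines <- vapply(seq_along(nm), function(i)
        paste(c(nm[i], descriptions[i], catalog@sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write / read a count experiment as TSV
#'
#' `writeCounts` writes a genes-by-samples TSV (first column `gene`, header
#' of sample ids) plus a sample-sheet TSV (`sample_id`, `pair_id`,
#' `condition`); `readCounts` rebuilds the [RegenExperiment-class].
#'
#' @param x a [RegenExperiment-class].
#' @param countsPath,sampleSheetPath file paths.
#' @return `readCounts`: a [RegenExperiment-class]; `writeCounts`: invisible
#'   `NULL`.
#' @export
writeCounts <- function(x, countsPath, sampleSheetPath) {
    cts <- counts(x)
    df <- data.frame(gene = rownames(cts), cts, check.names = FALSE)
    utils::write.table(df, countsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- SummarizedExperiment::colData(x)
    utils::write.table(
        data.frame(sample_id = rownames(cd), pair_id = cd$pairId,
                   condition = cd$condition),
        sampleSheetPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' @rdname writeCounts
#' @export
readCounts <- function(countsPath, sampleSheetPath) {
    df <- utils::read.delim(countsPath, check.names = FALSE)
    cts <- as.matrix(df[, -1L, drop = FALSE])
    rownames(cts) <- df[[1L]]
    sheet <- utils::read.delim(sampleSheetPath)
    RegenExperiment(cts, sheet)
}

#' Write a contrast table as TSV
#'
#' Columns: `gene`, `base_mean`, `log2fc`, `se`, `wald_stat`, `p_value`,
#' `fdr`; missing values as `NA`.
#'
#' @param tab a [ContrastTable-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeContrastTable <- function(tab, path) {
    df <- data.frame(gene = rownames(tab), base_mean = tab$baseMean,
                     log2fc = tab$log2FoldChange, se = tab$lfcSE,
                     wald_stat = tab$stat, p_value = tab$pvalue,
                     fdr = tab$fdr)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a contrast table written by [writeContrastTable()]
#' @param path file path.
#' @param pairId contrast label to attach.
#' @return A [ContrastTable-class].
#' @export
readContrastTable <- function(path, pairId) {
    df <- utils::read.delim(path)
    new("ContrastTable",
        DataFrame(baseMean = df$base_mean, log2FoldChange = df$log2fc,
                  lfcSE = df$se, stat = df$wald_stat, pvalue = df$p_value,
                  fdr = df$fdr, row.names = df$gene),
        pairId = pairId)
}

#' Write the planted-truth ledger as TSV
#' @param x a simulated [RegenExperiment-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeSimTruth <- function(x, path) {
    utils::write.table(as.data.frame(simTruth(x)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
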