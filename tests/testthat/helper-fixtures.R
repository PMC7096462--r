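# Fixture builders shared across test files. Everything is generated in
# code; no data files are read.

# A ContrastTable with prescribed statistics, for classifier/labeling tests.
makeContrastTable <- function(genes, log2fc, pvalue, fdr, pairId,
                              baseMean = 100) {
    methods::new("ContrastTable",
        S4Vectors::DataFrame(baseMean = rep_len(baseMean, length(genes)),
                             log2FoldChange = log2fc,
                             lfcSE = rep_len(0.1, length(genes)),
                             stat = log2fc / 0.1,
                             pvalue = pvalue, fdr = fdr,
                             row.names = genes),
        pairId = pairId)
}

# Contrast list where every pair carries the same per-gene stats except for
# named overrides: override[[pair]] = list(log2fc=, pvalue=, fdr=).
makePanelContrasts <- function(genes, default = list(log2fc = 0, pvalue = 0.9,
                                                     fdr = 0.9),
                               override = list(),
                               pairs = c("S1", "G2", "G3", "G4", "G5", "G6",
                                         "G7")) {
    n <- length(genes)
    out <- lapply(pairs, function(p) {
        v <- utils::modifyList(default, override[[p]] %||% list())
        makeContrastTable(genes, rep_len(v$log2fc, n), rep_len(v$pvalue, n),
                          rep_len(v$fdr, n), p)
    })
    names(out) <- pairs
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-condition experiment from an explicit count matrix.
makeExperiment <- function(cts, pairId = "S1") {
    colnames(cts) <- paste0("s", seq_len(ncol(cts)))
    if (is.null(rownames(cts))) rownames(cts) <- paste0("g", seq_len(nrow(cts)))
    half <- ncol(cts) / 2
    RegenExperiment(cts, data.frame(
        sample_id = colnames(cts), pair_id = pairId,
        condition = rep(c("wt", "mut"), each = half)))
}

# SimConfig with planted blocks scaled down for small gene counts.
smallSim <- function(nGenes, ...) {
    SimConfig(nGenes = nGenes, nSharedUp = as.integer(nGenes %/% 10),
              nSharedDown = as.integer(nGenes %/% 10),
              nSpecificPerPair = 2L, ...)
}
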