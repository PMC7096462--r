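#' Simulate a seven-contrast count experiment with planted truth
#'
#' Draws a negative-binomial gene-by-sample count matrix for a panel of
#' wildtype-vs-mutant contrasts with a planted signature: `nSharedUp` /
#' `nSharedDown` genes shifted by `+/- effectLog2FC` in every regeneration
#' contrast and untouched elsewhere, `nSpecificPerPair` genes shifted (random
#' sign) in exactly one contrast, and a null remainder. For gene g in sample
#' j of pair k the NB mean is
#' `baselineMean(g) * depth(j) * 2^trueLog2FC(g, k)` with
#' `variance = mu + dispersion * mu^2` (`dispersion = 0` falls back to
#' Poisson). Baseline means are log-normal, depth factors log-uniform on
#' `libSizeRange`. The draw is a pure function of the config (including its
#' seed); the caller's RNG state is left untouched.
#'
#' @param config a [SimConfig-class].
#' @return A [RegenExperiment-class]; `rowData()$category` and
#'   `rowData()$baselineMean` describe the planted design,
#'   `metadata()$trueLog2FC` is the gene-by-pair matrix of true log2 fold
#'   changes, `metadata()$simConfig` echoes `config`. Sample depth factors
#'   are in `colData()$depthFactor`.
#' @examples
#' re <- simulateCounts(SimConfig(nGenes = 300, seed = 7L))
#' table(SummarizedExperiment::rowData(re)$category)
#' @export
simulateCounts <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    nG <- config@nGenes
    pairs <- config@pairIds
    nRep <- config@nReplicates

    oldseed <- .GlobalEnv$.Random.seed
    on.exit({
        if (is.null(oldseed)) {
            if (exists(".Random.seed", envir = .GlobalEnv))
                rm(".Random.seed", envir = .GlobalEnv)
        } else assign(".Random.seed", oldseed, envir = .GlobalEnv)
    })
    set.seed(config@seed)

    genes <- sprintf("gene%05d", seq_len(nG))
    baseMu <- stats::rlnorm(nG, meanlog = config@meanLogMu,
                            sdlog = config@sdLogMu)

    # planted category assignment over a shuffled gene order
    nSpec <- config@nSpecificPerPair * length(pairs)
    shuffled <- sample.int(nG)
    category <- rep("null", nG)
    take <- function(k) {
        idx <- shuffled[seq_len(k)]
        shuffled <<- shuffled[-seq_len(k)]
        idx
    }
    idxUp <- take(config@nSharedUp)
    idxDown <- take(config@nSharedDown)
    category[idxUp] <- "shared_up"
    category[idxDown] <- "shared_down"
    specIdx <- if (nSpec > 0) take(nSpec) else integer()
    specPair <- rep(pairs, each = config@nSpecificPerPair)
    category[specIdx] <- paste0("specific:", specPair)
    # a zero effect size is a global null: no gene is truly perturbed
    if (config@effectLog2FC == 0) category[] <- "null"

    lfc <- matrix(0, nrow = nG, ncol = length(pairs),
                  dimnames = list(genes, pairs))
    lfc[idxUp, config@regenPairs] <- config@effectLog2FC
    lfc[idxDown, config@regenPairs] <- -config@effectLog2FC
    if (length(specIdx)) {
        sign <- sample(c(-1, 1), length(specIdx), replace = TRUE)
        lfc[cbind(specIdx, match(specPair, pairs))] <-
            sign * config@effectLog2FC
    }

    nSamp <- 2L * nRep * length(pairs)
    sampPair <- rep(pairs, each = 2L * nRep)
    sampCond <- rep(rep(c("wt", "mut"), each = nRep), length(pairs))
    sampId <- paste(sampPair, sampCond,
                    rep(seq_len(nRep), 2L * length(pairs)), sep = "_")
    depth <- exp(stats::runif(nSamp, log(config@libSizeRange[1L]),
                              log(config@libSizeRange[2L])))

    disp <- if (length(config@dispersion) == 1L)
        rep(config@dispersion, nG) else config@dispersion

    cts <- matrix(0L, nrow = nG, ncol = nSamp,
                  dimnames = list(genes, sampId))
    for (j in seq_len(nSamp)) {
        mu <- baseMu * depth[j]
        if (sampCond[j] == "mut")
            mu <- mu * 2^lfc[, sampPair[j]]
        pois <- disp == 0
        draw <- numeric(nG)
        if (any(pois)) draw[pois] <- stats::rpois(sum(pois), mu[pois])
        if (any(!pois)) draw[!pois] <- stats::rnbinom(
            sum(!pois), mu = mu[!pois], size = 1 / disp[!pois])
        cts[, j] <- as.integer(draw)
    }

    re <- RegenExperiment(cts, data.frame(
        sample_id = sampId, pair_id = sampPair, condition = sampCond))
    SummarizedExperiment::rowData(re)$category <- category
    SummarizedExperiment::rowData(re)$baselineMean <- baseMu
    SummarizedExperiment::colData(re)$depthFactor <- depth
    metadata(re)$trueLog2FC <- lfc
    metadata(re)$simConfig <- config
    re
}

#' @rdname simTruth
#' @export
setMethod("simTruth", "RegenExperiment", function(x) {
    lfc <- trueLog2FC(x)
    rd <- SummarizedExperiment::rowData(x)
    df <- DataFrame(gene = rownames(x), category = rd$category)
    for (p in colnames(lfc)) df[[paste0("lfc.", p)]] <- lfc[, p]
    df
})

#' @rdname simTruth
#' @export
setMethod("trueLog2FC", "RegenExperiment", function(x) {
    lfc <- metadata(x)$trueLog2FC
    if (is.null(lfc))
        stop("no planted truth: object was not produced by simulateCounts()")
    lfc
})

#' Simulate a gene-set catalog with planted enriched sets
#'
#' Builds `nSets` gene sets over the simulated gene universe. The first
#' `nEnrichedSets` ("planted") sets draw a fraction `enrichmentFraction` of
#' their members from the shared signature genes (`shared_up` and
#' `shared_down`) and the remainder uniformly from the rest of the universe;
#' all other sets are uniform draws. Set sizes are uniform on
#' `setSizeRange`. The catalog round-trips through GMT.
#'
#' @param x a simulated [RegenExperiment-class] (source of universe and
#'   planted genes).
#' @param nSets total number of sets.
#' @param setSizeRange integer range of set sizes.
#' @param nEnrichedSets number of planted sets.
#' @param enrichmentFraction fraction of planted-set members taken from the
#'   shared signature genes, in (0, 1]; 0 plants nothing.
#' @param seed integer seed, independent of the count simulation.
#' @return A [GeneSetCatalog-class] with `plantedSets()` naming the planted
#'   sets.
#' @export
simulateGeneSetCatalog <- function(x, nSets = 200L, setSizeRange = c(10L, 100L),
                                   nEnrichedSets = 10L,
                                   enrichmentFraction = 0.5, seed = 1L) {
    stopifnot(is(x, "RegenExperiment"))
    if (enrichmentFraction < 0 || enrichmentFraction > 1)
        stop("enrichmentFraction must lie in [0, 1]")
    uni <- rownames(x)
    if (max(setSizeRange) > length(uni))
        stop("set sizes exceed the universe")
    category <- SummarizedExperiment::rowData(x)$category
    pool <- uni[category %in% c("shared_up", "shared_down")]
    maxPlanted <- ceiling(max(setSizeRange) * enrichmentFraction)
    if (nEnrichedSets > 0L && enrichmentFraction > 0 && maxPlanted > length(pool))
        stop(sprintf(
            "planted sets need up to %d signature genes but only %d exist",
            maxPlanted, length(pool)))

    oldseed <- .GlobalEnv$.Random.seed
    on.exit({
        if (is.null(oldseed)) {
            if (exists(".Random.seed", envir = .GlobalEnv))
                rm(".Random.seed", envir = .GlobalEnv)
        } else assign(".Random.seed", oldseed, envir = .GlobalEnv)
    })
    set.seed(seed)

    nSets <- as.integer(nSets)
    nEnrichedSets <- as.integer(nEnrichedSets)
    sizes <- sample(seq(setSizeRange[1L], setSizeRange[2L]), nSets,
                    replace = TRUE)
    names <- sprintf("set%03d", seq_len(nSets))
    planted <- names[seq_len(nEnrichedSets)]
    sets <- vector("list", nSets)
    names(sets) <- names
    for (i in seq_len(nSets)) {
        if (i <= nEnrichedSets && enrichmentFraction > 0) {
            k <- round(sizes[i] * enrichmentFraction)
            members <- sample(pool, k)
            members <- c(members,
                         sample(setdiff(uni, members), sizes[i] - k))
        } else {
            members <- sample(uni, sizes[i])
        }
        sets[[i]] <- sort(members)
    }
    GeneSetCatalog(sets, universe = uni, planted = planted)
}
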