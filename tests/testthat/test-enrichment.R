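regen <- c("S1", "G3", "G5")
nonregen <- c("G2", "G4", "G6", "G7")

test_that("Fisher p matches the enumeration oracle and fisher.test", {
    # worked example: universe 20, set 12, foreground 5, overlap 4
    a <- 4; b <- 1; c <- 8; d <- 7
    expect_equal(fisherExactP(a, b, c, d), fisherOracle(a, b, c, d))
    expect_equal(fisherExactP(a, b, c, d),
                 fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
                 tolerance = 1e-12)
    set.seed(81)
    for (i in 1:50) {
        t <- as.list(rpois(4, 6))
        expect_equal(do.call(fisherExactP, t), do.call(fisherOracle, t))
        expect_equal(do.call(fisherExactP, t),
                     fisher.test(matrix(unlist(t), 2, byrow = TRUE))$p.value,
                     tolerance = 1e-9)
    }
})

test_that("degenerate foregrounds are reported, not tested away", {
    uni <- sprintf("g%02d", 1:20)
    catal <- GeneSetCatalog(list(all = uni), universe = uni)
    res <- fisherORA(uni, catal, minSet = 1)
    expect_equal(res$pvalue, 1)          # foreground = set = universe
    expect_identical(res$a, 20L)

    res0 <- fisherORA(character(), catal, minSet = 1)
    expect_equal(res0$pvalue, 1)         # empty foreground
    expect_match(S4Vectors::metadata(res0)$flag, "empty foreground")
})

test_that("size filters remove sets before testing", {
    uni <- sprintf("g%02d", 1:40)
    catal <- GeneSetCatalog(list(small = uni[1:9], ok = uni[1:12]),
                            universe = uni)
    res <- fisherORA(uni[1:6], catal, minSet = 10, maxSet = 500)
    expect_identical(res$failingFilter[res$set == "small"], "set_too_small")
    expect_true(is.na(res$pvalue[res$set == "small"]))
    expect_false(is.na(res$pvalue[res$set == "ok"]))
    # fdr computed across tested sets only
    expect_true(is.na(res$fdr[res$set == "small"]))
})

test_that("per-pair testing is a pure function of the DE list", {
    genes <- sprintf("g%03d", 1:60)
    tabs <- makePanelContrasts(genes, pairs = c("S1", "G3"),
        override = list(S1 = list(fdr = c(rep(0.01, 10), rep(0.9, 50))),
                        G3 = list(fdr = c(rep(0.01, 10), rep(0.9, 50)))))
    catal <- GeneSetCatalog(list(s1 = genes[1:15], s2 = genes[30:50]),
                            universe = genes)
    res <- perPairSetTest(tabs, catal, minSet = 10)
    s1 <- res[res$pairId == "S1", setdiff(colnames(res), "pairId")]
    g3 <- res[res$pairId == "G3", setdiff(colnames(res), "pairId")]
    expect_equal(as.data.frame(s1), as.data.frame(g3))

    # a pair with no DE genes yields p = 1 everywhere
    tabs$G3$fdr <- rep(0.9, 60)
    res <- perPairSetTest(tabs, catal, minSet = 10)
    expect_equal(res$pvalue[res$pairId == "G3"], c(1, 1))
})

test_that("the enriched-set rule and its filters match the worked example", {
    genes <- sprintf("g%03d", 1:200)
    catal <- GeneSetCatalog(list(hit = genes[1:50]), universe = genes)
    perPair <- do.call(rbind, lapply(c(regen, nonregen), function(p) {
        sig <- p == "S1"
        S4Vectors::DataFrame(set = "hit", setSize = 50L, a = 5L, b = 15L,
                             c = 45L, d = 135L,
                             oddsRatio = if (sig) 3 else 0.9,
                             pvalue = if (sig) 1e-5 else 0.6,
                             fdr = if (sig) 1e-3 else 0.8,
                             failingFilter = NA_character_, pairId = p)
    }))
    assoc <- genes[1:5]
    lab <- labelEnrichedSets(perPair, assoc, catal)
    expect_true(lab$enriched)
    expect_identical(lab$qualifyingPairs, "S1")

    # with only 2 associated members the set is removed
    lab2 <- labelEnrichedSets(perPair, genes[1:2], catal)
    expect_false(lab2$enriched)
    expect_identical(lab2$failingFilter, "too_few_associated_members")

    # missing pair results are an error
    expect_error(labelEnrichedSets(perPair[perPair$pairId != "G7", ],
                                   assoc, catal), "G7")
})

test_that("enrichment labels match the straight-line oracle on a grid", {
    orX <- c(0.8, 1.5)
    pX <- c(1e-4, 0.05, 0.6)
    fdrX <- c(0.05, 0.2)
    pJ <- c(1e-5, 0.3)
    grid <- expand.grid(orX = orX, pX = pX, fdrX = fdrX, pJ = pJ)
    genes <- sprintf("g%03d", 1:100)
    for (reading in c("significance", "literal")) {
        for (i in seq_len(nrow(grid))) {
            g <- grid[i, ]
            catal <- GeneSetCatalog(list(s = genes[1:20]), universe = genes)
            perPair <- do.call(rbind, lapply(c(regen, nonregen), function(p) {
                isR <- p %in% regen
                S4Vectors::DataFrame(set = "s", setSize = 20L, a = 4L,
                                     b = 6L, c = 16L, d = 74L,
                                     oddsRatio = if (isR) g$orX else 1.2,
                                     pvalue = if (isR) g$pX else g$pJ,
                                     fdr = if (isR) g$fdrX else 0.5,
                                     failingFilter = NA_character_,
                                     pairId = p)
            }))
            lab <- labelEnrichedSets(perPair, genes[1:4], catal,
                                     reading = reading)
            or <- p <- fdr <- setNames(numeric(7), c(regen, nonregen))
            or[regen] <- g$orX; or[nonregen] <- 1.2
            p[regen] <- g$pX; p[nonregen] <- g$pJ
            fdr[regen] <- g$fdrX; fdr[nonregen] <- 0.5
            want <- labelOracle(or, p, fdr, regen, nonregen, setSize = 20,
                                assocCount = 4,
                                significanceReading =
                                    reading == "significance")
            expect_identical(lab$enriched, want)
        }
    }
})

test_that("relaxing the filters can only grow the enriched list", {
    re <- simulateCounts(SimConfig(nGenes = 800, seed = 23L))
    contrasts <- runContrasts(re)
    uni <- testedUniverse(contrasts)
    catal <- simulateGeneSetCatalog(re, nSets = 60L, nEnrichedSets = 8L,
                                    seed = 24L)
    catal <- GeneSetCatalog(geneSets(catal), uni, plantedSets(catal))
    assoc <- callRegenerationAssociated(classifyGenes(contrasts), "union")
    associated <- intersect(c(assoc$up, assoc$down), uni)
    perPair <- perPairSetTest(contrasts, catal, minSet = 5)
    strict <- labelEnrichedSets(perPair, associated, catal,
                                config = EnrichmentConfig(minSet = 10,
                                                          maxSet = 100,
                                                          minAssoc = 3))
    loose <- labelEnrichedSets(perPair, associated, catal,
                               config = EnrichmentConfig(minSet = 5,
                                                         maxSet = 500,
                                                         minAssoc = 1))
    expect_true(all(strict$set[strict$enriched] %in%
                    loose$set[loose$enriched]))
})
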