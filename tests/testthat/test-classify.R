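regen <- c("S1", "G3", "G5")
nonregen <- c("G2", "G4", "G6", "G7")

test_that("a cleanly specific gene is labeled up; the FDR boundary is strict", {
    contrasts <- makePanelContrasts("gene1",
        override = list(S1 = list(log2fc = 1, pvalue = 1e-4, fdr = 0.01)))
    calls <- classifyGenes(contrasts)
    expect_identical(calls["gene1", "S1"], "up")
    expect_identical(calls["gene1", "G3"], "none")

    # fdr exactly at the cutoff does not qualify (strict <)
    boundary <- makePanelContrasts("gene1",
        override = list(S1 = list(log2fc = 1, pvalue = 1e-4, fdr = 0.05)))
    expect_identical(classifyGenes(boundary)["gene1", "S1"], "none")
})

test_that("non-significance and margin clauses must hold in every control", {
    base <- list(S1 = list(log2fc = 1, pvalue = 1e-4, fdr = 0.01))
    # one control significant (p < 0.1) kills the label
    c1 <- makePanelContrasts("g", override = c(base, list(
        G4 = list(log2fc = 0, pvalue = 0.05, fdr = 0.9))))
    expect_identical(classifyGenes(c1)["g", "S1"], "none")
    # one control with fdr < 0.25 kills the label
    c2 <- makePanelContrasts("g", override = c(base, list(
        G6 = list(log2fc = 0, pvalue = 0.2, fdr = 0.2))))
    expect_identical(classifyGenes(c2)["g", "S1"], "none")
    # one control too close in fold change (margin 0.2) kills the label
    c3 <- makePanelContrasts("g", override = c(base, list(
        G2 = list(log2fc = 0.85, pvalue = 0.9, fdr = 0.9))))
    expect_identical(classifyGenes(c3)["g", "S1"], "none")
    c4 <- makePanelContrasts("g", override = c(base, list(
        G2 = list(log2fc = 0.79, pvalue = 0.9, fdr = 0.9))))
    expect_identical(classifyGenes(c4)["g", "S1"], "up")
})

test_that("mirrored and literal margins differ exactly for extreme controls", {
    # down gene; every control even more strongly down (but not significant):
    # the literal printed inequality tolerates this, the mirrored one rejects
    contrasts <- makePanelContrasts("g",
        default = list(log2fc = -3, pvalue = 0.15, fdr = 0.5),
        override = list(S1 = list(log2fc = -1, pvalue = 1e-4, fdr = 0.01),
                        G3 = list(log2fc = 0, pvalue = 0.9, fdr = 0.9),
                        G5 = list(log2fc = 0, pvalue = 0.9, fdr = 0.9)))
    expect_identical(classifyGenes(contrasts, margin = "mirrored")["g", "S1"],
                     "none")
    expect_identical(classifyGenes(contrasts, margin = "literal")["g", "S1"],
                     "down")
})

test_that("label sets match the straight-line oracle on a threshold grid", {
    fdrX <- c(0.01, 0.05, 0.2)
    lfcX <- c(-1.5, 0.5, 1.5)
    pJ <- c(0.05, 0.1, 0.5)
    fdrJ <- c(0.2, 0.25, 0.8)
    lfcJ <- c(-1.4, 0.25, 1.35)
    grid <- expand.grid(fdrX = fdrX, lfcX = lfcX, pJ = pJ, fdrJ = fdrJ,
                        lfcJ = lfcJ)
    for (X in regen) {
        genes <- sprintf("g%03d", seq_len(nrow(grid)))
        override <- list()
        override[[X]] <- list(log2fc = grid$lfcX, pvalue = 1e-4,
                              fdr = grid$fdrX)
        for (j in nonregen)
            override[[j]] <- list(log2fc = grid$lfcJ, pvalue = grid$pJ,
                                  fdr = grid$fdrJ)
        contrasts <- makePanelContrasts(genes, override = override)
        calls <- classifyGenes(contrasts)
        for (i in seq_len(nrow(grid))) {
            lfc <- p <- fdr <- setNames(numeric(7), c(regen, nonregen))
            lfc[] <- 0; p[] <- 0.9; fdr[] <- 0.9
            lfc[X] <- grid$lfcX[i]; p[X] <- 1e-4; fdr[X] <- grid$fdrX[i]
            lfc[nonregen] <- grid$lfcJ[i]; p[nonregen] <- grid$pJ[i]
            fdr[nonregen] <- grid$fdrJ[i]
            want <- classifyOracle(lfc, p, fdr, regen, nonregen)
            got <- calls[genes[i], X]
            wantX <- if (paste0(X, "-up") %in% want) "up"
                     else if (paste0(X, "-down") %in% want) "down" else "none"
            expect_identical(got, wantX)
        }
    }
})

test_that("threshold changes move label sets monotonically", {
    set.seed(61)
    n <- 300
    genes <- sprintf("g%03d", 1:n)
    override <- list()
    for (p in c(regen, nonregen))
        override[[p]] <- list(log2fc = rnorm(n), pvalue = runif(n),
                              fdr = runif(n))
    contrasts <- makePanelContrasts(genes, override = override)
    labelSet <- function(thr) {
        calls <- classifyGenes(contrasts, thresholds = thr)
        which(as.matrix(as.data.frame(calls[, regen])) != "none")
    }
    base <- labelSet(SignatureThresholds())
    expect_true(all(labelSet(SignatureThresholds(fdrSig = 0.01)) %in% base))
    expect_true(all(labelSet(SignatureThresholds(pNonsig = 0.3)) %in% base))
    expect_true(all(labelSet(SignatureThresholds(fdrNonsig = 0.5)) %in% base))
    expect_true(all(labelSet(SignatureThresholds(marginLog2 = 0.6)) %in% base))
})

test_that("labels are sign-coherent and aggregation modes behave as defined", {
    re <- simulateCounts(SimConfig(nGenes = 600, seed = 17L))
    contrasts <- runContrasts(re)
    calls <- classifyGenes(contrasts)
    lfcS1 <- contrasts$S1$log2FoldChange
    expect_true(all(lfcS1[calls$S1 == "up"] > 0))
    expect_true(all(lfcS1[calls$S1 == "down"] < 0))

    inter <- callRegenerationAssociated(calls, "intersection")
    uni <- callRegenerationAssociated(calls, "union")
    expect_true(all(inter$up %in% uni$up))
    expect_true(all(inter$down %in% uni$down))
    # intersection mode cannot label a gene both ways (union mode can:
    # up in one regeneration contrast, down in another)
    expect_length(intersect(inter$up, inter$down), 0)

    # definitional cases on crafted labels
    craft <- makePanelContrasts(c("all3", "only1"),
        override = list(S1 = list(log2fc = c(1, 1), pvalue = 1e-4,
                                  fdr = 0.01),
                        G3 = list(log2fc = c(1, 0), pvalue = c(1e-4, 0.9),
                                  fdr = c(0.01, 0.9)),
                        G5 = list(log2fc = c(1, 0), pvalue = c(1e-4, 0.9),
                                  fdr = c(0.01, 0.9))))
    cc <- classifyGenes(craft)
    expect_identical(callRegenerationAssociated(cc, "intersection")$up, "all3")
    expect_setequal(callRegenerationAssociated(cc, "union")$up,
                    c("all3", "only1"))
})

test_that("genes untested in any contrast are excluded, not imputed", {
    contrasts <- makePanelContrasts(c("g1", "g2"),
        override = list(S1 = list(log2fc = c(1, 1), pvalue = 1e-4,
                                  fdr = 0.01)))
    contrasts$G4$pvalue[1] <- NA
    contrasts$G4$fdr[1] <- NA
    contrasts$G4$log2FoldChange[1] <- NA
    calls <- classifyGenes(contrasts)
    expect_false(calls["g1", "testable"])
    expect_identical(calls["g1", "S1"], "none")
    expect_true(calls["g2", "testable"])
    expect_identical(calls["g2", "S1"], "up")
})
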