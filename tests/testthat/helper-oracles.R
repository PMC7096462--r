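# Independent brute-force oracles. These deliberately share no code with the
# package: scalar loops and direct enumeration only.

# O(m^2) Benjamini-Hochberg: for each p_i, the minimum over all p_j >= p_i of
# m * p_j / rank(p_j), capped at 1.
bhOracle <- function(p) {
    m <- length(p)
    rank <- vapply(p, function(x) sum(p <= x), numeric(1))
    vapply(seq_len(m), function(i) {
        cand <- which(p >= p[i])
        min(1, min(m * p[cand] / rank[cand]))
    }, numeric(1))
}

# Two-sided Fisher exact p by direct enumeration of all tables with the
# observed margins, using factorial-based table probabilities.
fisherOracle <- function(a, b, c, d) {
    N <- a + b + c + d
    n <- a + b      # foreground margin
    K <- a + c      # set margin
    tabProb <- function(x)
        exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
    support <- max(0, n + K - N):min(n, K)
    probs <- vapply(support, tabProb, numeric(1))
    pObs <- probs[support == a]
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# Straight-line scalar re-implementation of the cross-contrast rule for one
# gene. lfc/p/fdr are named vectors over all pairs.
classifyOracle <- function(lfc, p, fdr, regen, nonregen,
                           fdrSig = 0.05, pNonsig = 0.1, fdrNonsig = 0.25,
                           margin = 0.2, mirrored = TRUE) {
    labels <- character(0)
    nonsig <- TRUE
    for (j in nonregen)
        if (!(p[j] >= pNonsig && fdr[j] >= fdrNonsig)) nonsig <- FALSE
    for (X in regen) {
        if (fdr[X] < fdrSig && lfc[X] > 0 && nonsig) {
            ok <- TRUE
            for (j in nonregen) if (!(lfc[j] <= lfc[X] - margin)) ok <- FALSE
            if (ok) labels <- c(labels, paste0(X, "-up"))
        }
        if (fdr[X] < fdrSig && lfc[X] < 0 && nonsig) {
            ok <- TRUE
            for (j in nonregen) {
                cond <- if (mirrored) lfc[j] >= lfc[X] + margin
                        else lfc[j] <= lfc[X] + margin
                if (!cond) ok <- FALSE
            }
            if (ok) labels <- c(labels, paste0(X, "-down"))
        }
    }
    labels
}

# Straight-line re-implementation of the enriched-set labeling rule for one
# set. or/p/fdr are named vectors over all pairs.
labelOracle <- function(or, p, fdr, regen, nonregen, setSize, assocCount,
                        sigFdr = 0.1, sigP = 0.01, minSet = 10, maxSet = 500,
                        minAssoc = 3, significanceReading = TRUE) {
    if (setSize < minSet || setSize > maxSet) return(FALSE)
    if (assocCount < minAssoc) return(FALSE)
    qualP <- c()
    for (X in regen) {
        sig <- if (significanceReading) (fdr[X] < sigFdr || p[X] < sigP)
               else (fdr[X] > sigFdr || p[X] > sigP)
        if (or[X] > 1 && sig) qualP <- c(qualP, p[X])
    }
    if (!length(qualP)) return(FALSE)
    for (j in nonregen) if (!(p[j] > min(qualP))) return(FALSE)
    TRUE
}

# Naive O(n^3) agglomeration: distances recomputed from scratch between the
# current clusters at every step (no Lance-Williams update), same
# lexicographic tie-break definition as the package documents.
naiveLinkage <- function(d0, labels, linkage = "average") {
    clusters <- lapply(seq_along(labels), function(i) i)
    codes <- -seq_along(labels)
    merges <- NULL
    heights <- c()
    clusterDist <- function(A, B) {
        vals <- c()
        for (i in A) for (j in B) vals <- c(vals, d0[i, j])
        if (linkage == "average") mean(vals) else max(vals)
    }
    while (length(clusters) > 1L) {
        best <- NULL
        for (ii in seq_along(clusters)) for (jj in seq_along(clusters)) {
            if (ii >= jj) next
            dij <- clusterDist(clusters[[ii]], clusters[[jj]])
            key <- sort(c(min(labels[clusters[[ii]]]),
                          min(labels[clusters[[jj]]])))
            better <- is.null(best) || dij < best$d - 1e-12 ||
                (abs(dij - best$d) <= 1e-12 &&
                 (key[1] < best$key[1] ||
                  (key[1] == best$key[1] && key[2] < best$key[2])))
            if (better) best <- list(ii = ii, jj = jj, d = dij, key = key)
        }
        merges <- rbind(merges, sort(c(codes[best$ii], codes[best$jj])))
        heights <- c(heights, best$d)
        clusters[[best$ii]] <- c(clusters[[best$ii]], clusters[[best$jj]])
        codes[best$ii] <- length(heights)
        clusters[[best$jj]] <- NULL
        codes <- codes[-best$jj]
    }
    list(merges = unname(merges), heights = heights)
}
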