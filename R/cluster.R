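#' @include AllClasses.R
NULL

#' Gene-by-contrast log2 fold-change profile matrix
#'
#' Stacks the `log2FoldChange` columns of the given contrasts, restricted to
#' genes with a defined (tested) fold change in every contrast, in the order
#' the contrasts are supplied.
#'
#' @param contrasts named list of [ContrastTable-class] (>= 2).
#' @return Numeric matrix, genes x pairs, no missing values.
#' @export
buildProfileMatrix <- function(contrasts) {
    if (length(contrasts) < 2L)
        stop("need at least 2 contrasts to build a profile matrix")
    lfc <- .contrastMatrix(contrasts, names(contrasts), "log2FoldChange")
    lfc[rowSums(is.na(lfc)) == 0L, , drop = FALSE]
}

.profileDistance <- function(profiles, metric) {
    if (metric == "correlation") {
        sds <- apply(profiles, 2L, stats::sd)
        if (any(sds == 0))
            stop("zero-variance profile column(s) under correlation metric: ",
                 paste(colnames(profiles)[sds == 0], collapse = ", "))
        d <- 1 - stats::cor(profiles)
    } else {
        d <- as.matrix(stats::dist(t(profiles)))
    }
    diag(d) <- 0
    d
}

#' Hierarchical clustering of contrasts on fold-change profiles
#'
#' Agglomerative clustering of the profile-matrix columns (one per
#' wildtype-mutant contrast), mirroring the sample dendrogram built from
#' log2 fold changes of normalized read counts. Distances are
#' `1 - Pearson r` between columns (default) or Euclidean; linkage is
#' average (default) or complete, updated by the Lance-Williams recurrence.
#' Ties in the minimum inter-cluster distance are broken deterministically
#' by merging the pair whose smallest leaf labels sort first.
#'
#' @param profiles matrix from [buildProfileMatrix()].
#' @param metric `"correlation"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return A [LinkageTree-class].
#' @examples
#' re <- simulateCounts(SimConfig(nGenes = 500, seed = 2L))
#' tree <- clusterContrasts(buildProfileMatrix(runContrasts(re)))
#' treeToNewick(tree)
#' @export
clusterContrasts <- function(profiles,
                             metric = c("correlation", "euclidean"),
                             linkage = c("average", "complete")) {
    metric <- match.arg(metric)
    linkage <- match.arg(linkage)
    labels <- colnames(profiles)
    n <- length(labels)
    if (n < 2L) stop("need at least 2 columns to cluster")
    d <- .profileDistance(profiles, metric)

    # active clusters keyed by node code (hclust convention: -leaf or merge row)
    code <- -seq_len(n)
    size <- rep(1L, n)
    minLab <- labels                 # lexicographic tie-break key per cluster
    merges <- matrix(0L, n - 1L, 2L)
    heights <- numeric(n - 1L)
    active <- seq_len(n)

    for (s in seq_len(n - 1L)) {
        best <- NULL
        bestD <- Inf
        for (ii in seq_along(active)[-length(active)]) {
            for (jj in seq((ii + 1L), length(active))) {
                i <- active[ii]; j <- active[jj]
                dij <- d[i, j]
                key <- sort(c(minLab[i], minLab[j]))
                if (dij < bestD - 1e-12 ||
                    (abs(dij - bestD) <= 1e-12 && !is.null(best) &&
                     .lexLess(key, best$key))) {
                    best <- list(i = i, j = j, key = key)
                    bestD <- dij
                }
            }
        }
        i <- best$i; j <- best$j
        merges[s, ] <- sort(c(code[i], code[j]))
        heights[s] <- max(bestD, 0)
        # Lance-Williams update into slot i
        for (k in setdiff(active, c(i, j))) {
            dk <- if (linkage == "average")
                (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
            else max(d[i, k], d[j, k])
            d[i, k] <- d[k, i] <- dk
        }
        size[i] <- size[i] + size[j]
        code[i] <- s
        minLab[i] <- min(minLab[i], minLab[j])
        active <- setdiff(active, j)
    }
    new("LinkageTree", merges = merges, heights = heights, labels = labels,
        method = linkage, metric = metric)
}

.lexLess <- function(a, b) {
    if (a[1L] != b[1L]) a[1L] < b[1L] else a[2L] < b[2L]
}

#' Leaf sets of each merge node
#' @noRd
.nodeLeaves <- function(tree, node) {
    if (node < 0L) return(-node)
    c(.nodeLeaves(tree, tree@merges[node, 1L]),
      .nodeLeaves(tree, tree@merges[node, 2L]))
}

#' Members of the smallest clade containing a label set
#'
#' Walks the merge sequence to the first node whose leaves cover all of
#' `labels` and returns that clade's labels - the standard check that a
#' group of contrasts forms its own subtree.
#'
#' @param tree a [LinkageTree-class].
#' @param labels leaf labels that must be covered.
#' @return Character vector of the smallest covering clade's labels.
#' @export
smallestClade <- function(tree, labels) {
    stopifnot(all(labels %in% tree@labels))
    want <- match(labels, tree@labels)
    for (s in seq_along(tree@heights)) {
        leaves <- .nodeLeaves(tree, s)
        if (all(want %in% leaves)) return(tree@labels[sort(leaves)])
    }
    tree@labels
}

#' Serialize a linkage tree as Newick
#'
#' Branch lengths place each leaf at depth `height/2` of its clade's merge,
#' the usual ultrametric dendrogram drawing, so a two-leaf tree at height h
#' reads `(A:h/2,B:h/2);`.
#'
#' @param tree a [LinkageTree-class].
#' @return Newick string (with trailing `;`).
#' @export
treeToNewick <- function(tree) {
    h <- function(node) if (node < 0L) 0 else tree@heights[node]
    rec <- function(node, parentH) {
        len <- (parentH - h(node)) / 2
        if (node < 0L)
            sprintf("%s:%g", tree@labels[-node], len)
        else
            sprintf("(%s,%s):%g", rec(tree@merges[node, 1L], h(node)),
                    rec(tree@merges[node, 2L], h(node)), len)
    }
    root <- nrow(tree@merges)
    sprintf("(%s,%s);", rec(tree@merges[root, 1L], h(root)),
            rec(tree@merges[root, 2L], h(root)))
}

#' Convert a LinkageTree to a base-R hclust object
#'
#' Useful for plotting with [stats::plot.hclust] or cutting with
#' [stats::cutree].
#'
#' @param tree a [LinkageTree-class].
#' @return An object of class `hclust`.
#' @export
asHclust <- function(tree) {
    root <- nrow(tree@merges)
    order <- .nodeLeaves(tree, root)
    structure(list(merge = tree@merges, height = tree@heights,
                   order = order, labels = tree@labels,
                   method = tree@method,
                   dist.method = tree@metric),
              class = "hclust")
}

#' Merge table of a linkage tree
#'
#' @param tree a [LinkageTree-class].
#' @return data.frame with columns `node_a`, `node_b`, `height`, `size`
#'   (hclust node coding).
#' @export
mergeTable <- function(tree) {
    sizes <- vapply(seq_along(tree@heights),
                    function(s) length(.nodeLeaves(tree, s)), integer(1))
    data.frame(node_a = tree@merges[, 1L], node_b = tree@merges[, 2L],
               height = tree@heights, size = sizes)
}
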