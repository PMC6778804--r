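# Experiment-level clustering: centered unscaled PCA, complete-linkage
# hierarchical clustering with Chebyshev distance, and exact optimal leaf
# ordering (minimum sum of adjacent-leaf distances over all subtree flips).

#' Sample scores from centered, unscaled PCA
#'
#' Samples are observations and genes are features; features are
#' centered but not scaled. Returns the scores on the first
#' `min(n_components, samples - 1)` components.
#'
#' @param logcounts Genes x samples matrix of normalized, log2-scale
#'   counts.
#' @param n_components Number of components to keep (default 6).
#' @return Samples x components score matrix.
#' @examples
#' cfg <- simConfig(n_genes = 50, n_bootstraps = 5, seed = 6)
#' sim <- normalizeCounts(simulateCounts(generateTruth(cfg), cfg))
#' dim(pcaSamples(SummarizedExperiment::assay(sim, "logcounts")))
#' @export
pcaSamples <- function(logcounts, n_components = 6L) {
    logcounts <- as.matrix(logcounts)
    if (ncol(logcounts) < 2L)
        stop("need at least 2 samples")
    pr <- prcomp(t(logcounts), center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(logcounts) - 1L, ncol(pr$x))
    pr$x[, seq_len(k), drop = FALSE]
}

#' Chebyshev (maximum-coordinate) distance matrix
#'
#' @param scores Samples x features matrix.
#' @return A `dist` object.
#' @examples
#' chebyshevDist(rbind(a = c(0, 0), b = c(1, 3)))
#' @export
chebyshevDist <- function(scores) {
    dist(scores, method = "maximum")
}

# Exact optimal leaf ordering for an hclust tree: dynamic program over
# (subtree, leftmost leaf, rightmost leaf), minimizing the sum of
# distances between adjacent leaves over all 2^(n-1) flip configurations.
.optimalLeafOrder <- function(hc, d) {
    dm <- as.matrix(d)
    merges <- hc$merge
    nodes <- vector("list", nrow(merges))
    leafNode <- function(i)
        list(leaves = i, cost = matrix(0, 1L, 1L), ord = list(list(i)))
    getNode <- function(ref)
        if (ref < 0) leafNode(-ref) else nodes[[ref]]
    for (v in seq_len(nrow(merges))) {
        L <- getNode(merges[v, 1L])
        R <- getNode(merges[v, 2L])
        leaves <- c(L$leaves, R$leaves)
        nl <- length(leaves)
        cost <- matrix(Inf, nl, nl)
        ord <- lapply(seq_len(nl), function(i) vector("list", nl))
        for (halves in list(list(L, R), list(R, L))) {
            A <- halves[[1L]]; B <- halves[[2L]]
            offA <- match(A$leaves, leaves)
            offB <- match(B$leaves, leaves)
            for (ui in seq_along(A$leaves)) {
                for (wi in seq_along(B$leaves)) {
                    best <- Inf; bestOrd <- NULL
                    for (hi in seq_along(A$leaves)) {
                        cA <- A$cost[ui, hi]
                        if (!is.finite(cA)) next
                        h <- A$leaves[hi]
                        for (ki in seq_along(B$leaves)) {
                            cB <- B$cost[ki, wi]
                            if (!is.finite(cB)) next
                            tot <- cA + dm[h, B$leaves[ki]] + cB
                            if (tot < best) {
                                best <- tot
                                bestOrd <- c(A$ord[[ui]][[hi]],
                                             B$ord[[ki]][[wi]])
                            }
                        }
                    }
                    iu <- offA[ui]; iw <- offB[wi]
                    if (best < cost[iu, iw]) {
                        cost[iu, iw] <- best
                        ord[[iu]][[iw]] <- bestOrd
                    }
                }
            }
        }
        nodes[[v]] <- list(leaves = leaves, cost = cost, ord = ord)
    }
    root <- nodes[[nrow(merges)]]
    ij <- which(root$cost == min(root$cost), arr.ind = TRUE)[1L, ]
    unlist(root$ord[[ij[1L]]][[ij[2L]]])
}

#' Sum of distances between adjacent leaves of an ordering
#'
#' @param order Integer or character leaf ordering.
#' @param d A `dist` object or distance matrix over the leaves.
#' @return The adjacency objective (scalar).
#' @examples
#' leafOrderObjective(1:3, dist(c(0, 1, 10)))
#' @export
leafOrderObjective <- function(order, d) {
    dm <- as.matrix(d)
    sum(dm[cbind(order[-length(order)], order[-1L])])
}

#' Complete-linkage Chebyshev clustering with optimal leaf ordering
#'
#' Clusters samples by complete linkage on the Chebyshev distance of
#' their scores, then rotates subtrees ("optimal swiveling") so that the
#' sum of distances between adjacent leaves is minimal over all
#' `2^(n-1)` flip configurations (exact dynamic program over subtree
#' end-leaves).
#'
#' @param scores Samples x features matrix (e.g. from [pcaSamples()]).
#' @return An `hclust` object; `$order` holds the optimal leaf order and
#'   `$dist` the Chebyshev `dist` used.
#' @examples
#' hc <- hclustCheb(rbind(a = 0, b = 1, c = 10))
#' hc$order
#' @export
hclustCheb <- function(scores) {
    scores <- as.matrix(scores)
    if (nrow(scores) < 2L)
        stop("need at least 2 samples")
    d <- chebyshevDist(scores)
    hc <- hclust(d, method = "complete")
    hc$order <- as.integer(.optimalLeafOrder(hc, d))
    hc$dist <- d
    hc
}

# Serialize an hclust tree to Newick with branch lengths equal to
# merge-height differences and children ordered to match hc$order.
.newickFromHclust <- function(hc) {
    labs <- hc$labels
    if (is.null(labs)) labs <- as.character(seq_along(hc$order))
    pos <- match(seq_along(hc$order), hc$order)  # leaf -> position
    rec <- function(ref, parentHeight) {
        if (ref < 0) {
            i <- -ref
            sprintf("%s:%g", labs[i], parentHeight)
        } else {
            h <- hc$height[ref]
            kids <- hc$merge[ref, ]
            first <- function(k) {
                if (k < 0) pos[-k] else min(pos[.leavesOf(hc, k)])
            }
            if (first(kids[1L]) > first(kids[2L]))
                kids <- rev(kids)
            sprintf("(%s,%s):%g", rec(kids[1L], h), rec(kids[2L], h),
                    parentHeight - h)
        }
    }
    root <- nrow(hc$merge)
    h <- hc$height[root]
    kids <- hc$merge[root, ]
    first <- function(k) if (k < 0) pos[-k] else min(pos[.leavesOf(hc, k)])
    if (first(kids[1L]) > first(kids[2L])) kids <- rev(kids)
    paste0("(", rec(kids[1L], h), ",", rec(kids[2L], h), ");")
}

.leavesOf <- function(hc, node) {
    if (node < 0) return(-node)
    c(.leavesOf(hc, hc$merge[node, 1L]),
      .leavesOf(hc, hc$merge[node, 2L]))
}

#' Write a dendrogram as Newick
#'
#' Branch lengths are merge-height differences (leaves sit at height 0);
#' children are ordered to match the tree's leaf order.
#'
#' @param hc An `hclust` object (e.g. from [hclustCheb()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeDendrogramNewick(hclustCheb(rbind(a = 0, b = 1, c = 10)), f)
#' readLines(f)
#' @export
writeDendrogramNewick <- function(hc, path) {
    writeLines(.newickFromHclust(hc), path)
    invisible(path)
}

#' Cluster the experiments of a dataset
#'
#' Convenience driver reproducing the experiment-clustering contract:
#' centered unscaled PCA on the normalized log2 counts, then
#' complete-linkage Chebyshev clustering of the top components with
#' optimal leaf ordering.
#'
#' @param x A normalized [SkinExperiment-class] (see
#'   [normalizeCounts()]).
#' @param n_components Components kept for clustering (default 6).
#' @return An `hclust` object as from [hclustCheb()].
#' @examples
#' cfg <- simConfig(n_genes = 60, n_bootstraps = 5, seed = 8)
#' sim <- normalizeCounts(simulateCounts(generateTruth(cfg), cfg))
#' clusterExperiments(sim)$order
#' @export
clusterExperiments <- function(x, n_components = 6L) {
    stopifnot(is(x, "SkinExperiment"))
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
        x <- normalizeCounts(x)
    logc <- SummarizedExperiment::assay(x, "logcounts")
    hclustCheb(pcaSamples(logc, n_components))
}
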