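# Fixture builders used across test files.

# A ConditionModel with prescribed condition means and standard errors
# (n = 1, all uncertainty booked as technical variance, so
# se = sqrt(v_tech) exactly).
toyModel <- function(means, ses = means * 0) {
    stopifnot(identical(dim(means), dim(ses)))
    conds <- validConditions()
    stopifnot(identical(colnames(means), conds$label))
    if (is.null(rownames(means)))
        rownames(means) <- sprintf("g%03d", seq_len(nrow(means)))
    rownames(ses) <- rownames(means)
    new("ConditionModel", means = means, techVar = ses^2,
        bioVarRaw = matrix(NA_real_, nrow(means), ncol(means),
                           dimnames = dimnames(means)),
        bioVar = means * 0, se = ses,
        nrep = rep(1L, ncol(means)), conditions = conds,
        sizeFactors = numeric(0), offset = 0.5)
}

# Means matrix over the 12 conditions, all equal to `base`.
flatMeans <- function(n_genes, base = 5) {
    conds <- validConditions()
    matrix(base, n_genes, nrow(conds),
           dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                           conds$label))
}

# A small simulated dataset (fast defaults for unit tests).
smallSim <- function(n_genes = 60, n_bootstraps = 20, seed = 99, ...) {
    cfg <- simConfig(n_genes = n_genes, n_bootstraps = n_bootstraps,
                     seed = seed, ...)
    simulateCounts(generateTruth(cfg), cfg)
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
enumHyperTail <- function(N, K, n, k) {
    idx <- seq_len(N)
    draws <- utils::combn(idx, n)
    hits <- colSums(draws <= K)   # first K elements are "term" genes
    mean(hits >= k)
}

# Brute-force optimal adjacency objective over all subtree flips of an
# hclust tree.
bruteForceFlipMin <- function(hc, d) {
    dm <- as.matrix(d)
    orders <- function(ref) {
        if (ref < 0) return(list(-ref))
        L <- orders(hc$merge[ref, 1L])
        R <- orders(hc$merge[ref, 2L])
        out <- list()
        for (a in L) for (b in R) {
            out[[length(out) + 1L]] <- c(a, b)
            out[[length(out) + 1L]] <- c(b, a)
        }
        out
    }
    all <- orders(nrow(hc$merge))
    min(vapply(all, leafOrderObjective, 0, d = dm))
}
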