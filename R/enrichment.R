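# Gene-set enrichment over flows, expressed-gene filtering, layer-specific
# gene ranking and heatmap-ready exports.

#' Expressed-gene filter
#'
#' A gene counts as expressed when its normalized, log2-transformed
#' condition-model mean reaches `tau` in at least one condition. The
#' default `tau = 2.5` corresponds to roughly 5.7 normalized counts on
#' the linear scale.
#'
#' @param model A [ConditionModel-class].
#' @param tau Log2-scale threshold (inclusive; default 2.5).
#' @return Character vector of gene ids passing the filter.
#' @examples
#' length(expressedGenes(exampleModel(n_genes = 40)))
#' @export
expressedGenes <- function(model, tau = 2.5) {
    stopifnot(is(model, "ConditionModel"))
    m <- condMeans(model)
    rownames(m)[apply(m, 1L, max) >= tau]
}

#' Hypergeometric gene-set enrichment of a flow pattern
#'
#' Tests whether `term` genes are over-represented among `pattern`
#' genes, relative to the `universe`: with `N = |universe|`,
#' `K = |term|`, `n = |pattern|` and overlap `k`, the p-value is the
#' exact upper tail `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, and
#' fold enrichment is `(k/n) / (K/N)`.
#'
#' @param termGenes,patternGenes Character vectors of gene ids; both
#'   must be subsets of `universe`.
#' @param universe Character vector: the gene universe.
#' @return One-row data.frame: `N`, `K`, `n`, `k`, `p`, `fold`,
#'   `empty_pattern` (TRUE with `p = 1`, `fold = NA` when the pattern is
#'   empty).
#' @examples
#' hypergeomEnrich(letters[1:5], letters[2:5], letters[1:10])
#' @export
hypergeomEnrich <- function(termGenes, patternGenes, universe) {
    termGenes <- unique(termGenes)
    patternGenes <- unique(patternGenes)
    universe <- unique(universe)
    if (!all(termGenes %in% universe))
        stop("term genes must be a subset of the universe")
    if (!all(patternGenes %in% universe))
        stop("pattern genes must be a subset of the universe")
    N <- length(universe)
    K <- length(termGenes)
    n <- length(patternGenes)
    k <- length(intersect(termGenes, patternGenes))
    if (n == 0L)
        return(data.frame(N = N, K = K, n = 0L, k = 0L, p = 1,
                          fold = NA_real_, empty_pattern = TRUE))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(N = N, K = K, n = n, k = k, p = p,
               fold = (k / n) / (K / N), empty_pattern = FALSE)
}

#' Enrichment of many gene sets across many flow patterns
#'
#' Runs [hypergeomEnrich()] over the full term x pattern grid. The
#' universe defaults to all genes in `calls`. Raw p-values are the
#' primary output (the retention rule of [enrichmentHeatmap()] operates
#' on them); a Benjamini-Hochberg column `p_adj` is emitted alongside.
#'
#' @param geneSets Named list of character vectors (term id -> member
#'   gene ids); see [readGeneSets()].
#' @param calls data.frame from [classifyFlows()].
#' @param patterns Character vector of flow query patterns.
#' @param universe Gene universe (default: all genes in `calls`).
#' @return data.frame with one row per (term, pattern): `term`,
#'   `pattern`, `N`, `K`, `n`, `k`, `p`, `fold`, `p_adj`.
#' @examples
#' calls <- classifyFlows(exampleModel(n_genes = 60))
#' sets <- list(t1 = calls$gene[1:10])
#' enrichFlows(sets, calls, c("S**", "NNN"))
#' @export
enrichFlows <- function(geneSets, calls, patterns, universe = NULL) {
    if (is.null(universe)) universe <- calls$gene
    geneSets <- lapply(geneSets, intersect, universe)
    rows <- list()
    for (tm in names(geneSets)) {
        for (q in patterns) {
            genes <- calls$gene[calls$flow %in% expandFlowQuery(q)]
            r <- hypergeomEnrich(geneSets[[tm]], genes, universe)
            r$term <- tm
            r$pattern <- q
            rows[[length(rows) + 1L]] <- r
        }
    }
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p, method = "BH")
    out[, c("term", "pattern", "N", "K", "n", "k", "p", "fold",
            "p_adj")]
}

#' Fold enrichment from printed summary counts
#'
#' `observed_fraction / (background_count / universe_size)`: how many
#' times more frequent a gene class is in a profile than expected at
#' random.
#'
#' @param observed_fraction Fraction of the profile in the class
#'   (in `[0, 1]`).
#' @param background_count Number of class genes in the universe.
#' @param universe_size Universe size.
#' @return The fold-enrichment ratio.
#' @examples
#' foldEnrichment(0.75, 2414, 31901)   # ~10x
#' @export
foldEnrichment <- function(observed_fraction, background_count,
                           universe_size) {
    stopifnot(observed_fraction >= 0, observed_fraction <= 1,
              background_count <= universe_size)
    if (background_count <= 0)
        stop("background count must be positive")
    observed_fraction / (background_count / universe_size)
}

#' Filtered -log10(p) matrix for enrichment heatmaps
#'
#' Pivots enrichment results to a term x pattern matrix of `-log10(p)`
#' and keeps every row and column containing at least one
#' `p <= p_cutoff`.
#'
#' @param results data.frame from [enrichFlows()].
#' @param p_cutoff Retention cutoff (default 1e-4).
#' @return Numeric matrix (possibly 0 x 0), rows = terms, columns =
#'   patterns, values `-log10(p)`.
#' @examples
#' calls <- classifyFlows(exampleModel(n_genes = 60))
#' res <- enrichFlows(list(t1 = calls$gene[1:5]), calls, "***")
#' enrichmentHeatmap(res, p_cutoff = 1)
#' @export
enrichmentHeatmap <- function(results, p_cutoff = 1e-4) {
    terms <- unique(results$term)
    pats <- unique(results$pattern)
    pm <- matrix(1, length(terms), length(pats),
                 dimnames = list(terms, pats))
    pm[cbind(match(results$term, terms),
             match(results$pattern, pats))] <- results$p
    keepR <- apply(pm <= p_cutoff, 1L, any)
    keepC <- apply(pm <= p_cutoff, 2L, any)
    -log10(pm[keepR, keepC, drop = FALSE])
}

#' Rank genes by skin enrichment plus layer specificity
#'
#' The skin score is `A - N`, where `A` is the mean of the three
#' `all_skin` condition means and `N` the mean of the three `nonskin1`
#' condition means; the layer score is the sum of absolute deviations
#' from the mean over the four layer conditions (basal and periderm at
#' 52 and 72 hpf). Genes are ordered by descending total (sum of the two
#' scores) with ties broken by gene id.
#'
#' @param model A [ConditionModel-class] over the full 12-condition
#'   design.
#' @param class_members Optional character vector restricting the table
#'   to a gene class.
#' @return data.frame ordered by descending `total`: `gene`,
#'   `skin_score`, `layer_score`, `total`, `rank`.
#' @examples
#' head(rankGenes(exampleModel(n_genes = 40)), 3)
#' @export
rankGenes <- function(model, class_members = NULL) {
    stopifnot(is(model, "ConditionModel"))
    m <- condMeans(model)
    need <- c(paste0("all_skin.", .TIMEPOINTS),
              paste0("nonskin1.", .TIMEPOINTS),
              .conditionLabel(rep(c("basal", "periderm"), each = 2L),
                              c("52hpf", "72hpf")))
    miss <- setdiff(need, colnames(m))
    if (length(miss))
        stop("condition missing from model: ", miss[1L])
    if (!is.null(class_members))
        m <- m[rownames(m) %in% class_members, , drop = FALSE]
    A <- rowMeans(m[, paste0("all_skin.", .TIMEPOINTS), drop = FALSE])
    N <- rowMeans(m[, paste0("nonskin1.", .TIMEPOINTS), drop = FALSE])
    lay <- m[, .conditionLabel(rep(c("basal", "periderm"), each = 2L),
                               c("52hpf", "72hpf")), drop = FALSE]
    layer <- rowSums(abs(lay - rowMeans(lay)))
    out <- data.frame(gene = rownames(m), skin_score = unname(A - N),
                      layer_score = unname(layer),
                      total = unname(A - N + layer),
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(-out$total, out$gene), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Mean-centered expression rows for heatmap export
#'
#' For each gene, the mean of its 12 condition-model means and the
#' residuals after subtracting it (on the linear scale the residuals
#' are fold changes relative to the gene's geometric mean across
#' conditions).
#'
#' @param model A [ConditionModel-class].
#' @param genes Gene ids to export (default all; order preserved).
#' @return A list with `row_means` (named vector) and `residuals`
#'   (genes x conditions matrix; rows sum to zero).
#' @examples
#' hm <- heatmapRows(exampleModel(n_genes = 10))
#' rowSums(hm$residuals)
#' @export
heatmapRows <- function(model, genes = NULL) {
    stopifnot(is(model, "ConditionModel"))
    m <- condMeans(model)
    if (!is.null(genes)) {
        miss <- setdiff(genes, rownames(m))
        if (length(miss))
            stop("unknown gene id: ", miss[1L])
        m <- m[genes, , drop = FALSE]
    }
    rm <- rowMeans(m)
    list(row_means = rm, residuals = m - rm)
}
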