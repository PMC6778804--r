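# Normalization, log2 transform, technical-variance estimation from
# bootstrap tensors, and the shrunken per-gene per-condition normal model.

.DEFAULT_OFFSET <- 0.5

# Median-of-ratios size factors against the per-gene geometric-mean
# reference, computed over genes with all-positive counts, then rescaled
# to geometric mean 1.
.sizeFactors <- function(counts) {
    if (ncol(counts) < 2L)
        stop("need at least 2 samples to normalize")
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos))
        stop("no gene has positive counts in every sample; ",
             "filter the matrix before normalizing")
    lref <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2L, function(col)
        exp(median(log(col) - lref)))
    sf / exp(mean(log(sf)))
}

#' Normalize expected counts and attach log2-transformed values
#'
#' Size factors are median-of-ratios against the per-gene geometric-mean
#' reference (computed over genes positive in all samples) and rescaled
#' so their geometric mean is 1. The transformed assay is
#' `log2(normalized + offset)`.
#'
#' @param x A [SkinExperiment-class] with assay `"counts"`.
#' @param offset Pseudo-count added before taking log2 (default 0.5).
#' @return `x` with assays `"normcounts"` and `"logcounts"` added,
#'   `colData` column `sizeFactor`, and the offset recorded in
#'   `metadata(x)$offset`.
#' @examples
#' cfg <- simConfig(n_genes = 30, n_bootstraps = 5, seed = 3)
#' sim <- normalizeCounts(simulateCounts(generateTruth(cfg), cfg))
#' SummarizedExperiment::colData(sim)$sizeFactor
#' @export
normalizeCounts <- function(x, offset = .DEFAULT_OFFSET) {
    stopifnot(is(x, "SkinExperiment"))
    cts <- SummarizedExperiment::assay(x, "counts")
    sf <- .sizeFactors(cts)
    norm <- sweep(cts, 2L, sf, "/")
    SummarizedExperiment::assay(x, "normcounts") <- norm
    SummarizedExperiment::assay(x, "logcounts") <-
        transformCounts(norm, offset = offset)
    SummarizedExperiment::colData(x)$sizeFactor <- sf
    S4Vectors::metadata(x)$offset <- offset
    x
}

#' Log2 transform with a fixed pseudo-count
#'
#' `transformCounts(x) = log2(x + offset)`; strictly increasing on
#' non-negative input. The default offset 0.5 makes `transformCounts(0)`
#' equal to -1 and `transformCounts(7.5)` equal to 3.
#'
#' @param x Non-negative numeric vector or matrix.
#' @param offset Pseudo-count (default 0.5).
#' @return Transformed values, same shape as `x`.
#' @examples
#' transformCounts(c(0, 7.5))
#' @export
transformCounts <- function(x, offset = .DEFAULT_OFFSET) {
    if (any(x < 0, na.rm = TRUE))
        stop("transformCounts needs non-negative input")
    log2(x + offset)
}

#' Transcripts-per-million from expected counts
#'
#' `TPM_g = 1e6 * (count_g / len_g) / sum_h (count_h / len_h)` per
#' sample; each sample's TPMs sum to one million.
#'
#' @param counts Genes x samples matrix of expected counts.
#' @param effective_lengths Per-gene positive effective lengths, in the
#'   row order of `counts`.
#' @return Genes x samples TPM matrix.
#' @examples
#' tpm(cbind(s1 = c(100, 300)), c(100, 300))
#' @export
tpm <- function(counts, effective_lengths) {
    counts <- as.matrix(counts)
    if (length(effective_lengths) != nrow(counts))
        stop("need one effective length per gene")
    if (any(effective_lengths <= 0))
        stop("effective lengths must be positive")
    rate <- counts / effective_lengths
    tot <- colSums(rate)
    if (any(tot == 0))
        stop("a sample has zero total rate; cannot compute TPM")
    sweep(rate, 2L, tot, "/") * 1e6
}

#' Technical variance per gene and condition from bootstrap tensors
#'
#' Each sample's bootstrap count matrix is normalized by the sample's
#' size factor and log2-transformed with the model offset; the per-gene
#' variance across the B bootstrap columns (unbiased, denominator B - 1)
#' estimates the technical variance of one observation. Condition-level
#' technical variance is the mean of the condition's per-sample
#' variances, weighting each replicate equally.
#'
#' @param x A normalized [SkinExperiment-class] (see [normalizeCounts()])
#'   carrying bootstrap matrices.
#' @return Genes x conditions matrix of technical variances.
#' @examples
#' cfg <- simConfig(n_genes = 30, n_bootstraps = 20, seed = 4)
#' sim <- normalizeCounts(simulateCounts(generateTruth(cfg), cfg))
#' head(technicalVariance(sim), 2)
#' @export
technicalVariance <- function(x) {
    stopifnot(is(x, "SkinExperiment"))
    bt <- bootstraps(x)
    if (!length(bt))
        stop("no bootstrap matrices attached")
    if (is.null(S4Vectors::metadata(x)$offset))
        stop("run normalizeCounts() first")
    offset <- S4Vectors::metadata(x)$offset
    sf <- SummarizedExperiment::colData(x)$sizeFactor
    names(sf) <- colnames(x)
    sheet <- sampleSheet(x)
    perSample <- vapply(names(bt), function(s) {
        z <- transformCounts(bt[[s]] / sf[[s]], offset = offset)
        z <- z - rowMeans(z)   # centered: no cancellation
        rowSums(z * z) / (ncol(z) - 1)
    }, numeric(nrow(x)))
    if (nrow(x) == 1L)
        perSample <- matrix(perSample, nrow = 1L,
                            dimnames = list(rownames(x), names(bt)))
    lab <- .conditionLabel(sheet$tissue, sheet$timepoint)
    names(lab) <- sheet$sample_id
    condLabs <- unique(lab)
    out <- vapply(condLabs, function(cl) {
        cols <- intersect(names(lab)[lab == cl], colnames(perSample))
        if (!length(cols))
            stop("condition ", cl, " has no bootstrap matrices")
        rowMeans(perSample[, cols, drop = FALSE])
    }, numeric(nrow(x)))
    if (nrow(x) == 1L)
        out <- matrix(out, nrow = 1L,
                      dimnames = list(rownames(x), condLabs))
    rownames(out) <- rownames(x)
    out
}

#' Empirical-Bayes shrinkage of raw biological variances
#'
#' Raw replicate variances with one or two degrees of freedom are noisy;
#' they are shrunk toward a smoothed mean-variance trend. The trend is
#' fit by lowess of `v_bio_raw + eps0` against the condition mean on the
#' variance scale (then logged), so its level is approximately unbiased
#' for the underlying variance; the blend is geometric,
#' `v_bio = exp(w log(v_bio_raw + eps0) + (1 - w) t(m)) - eps0`, floored
#' at zero, with weight `w = (n - 1) / (n - 1 + n0)` and prior weight
#' `n0 = 3`. Conditions with a single replicate (`w = 0`) take the trend
#' value. With fewer than 50 defined raw variances the trend falls back
#' to the global mean.
#'
#' @param v_bio_raw Numeric vector of raw biological variances (`NA`
#'   where undefined, i.e. `n = 1`).
#' @param m Condition means (same length).
#' @param n Replicate counts (same length).
#' @param n0 Prior weight (default 3).
#' @param eps0 Variance-scale regularizer (default 0.01).
#' @return Vector of shrunken variances, `>= 0` everywhere (including
#'   `n = 1` entries).
#' @examples
#' shrinkBiological(c(0.2, NA, 0.05), m = c(5, 6, 7), n = c(2, 1, 2))
#' @export
shrinkBiological <- function(v_bio_raw, m, n, n0 = 3, eps0 = 0.01) {
    stopifnot(length(v_bio_raw) == length(m), length(m) == length(n))
    def <- !is.na(v_bio_raw)
    if (sum(def) >= 50L) {
        # iter = 0: robustness iterations would track the median of the
        # few-df raw variances (~0.45x their mean) and bias the trend low
        fit <- lowess(m[def], v_bio_raw[def] + eps0, f = 0.5, iter = 0L)
        tv <- approx(fit$x, fit$y, xout = m, rule = 2L, ties = mean)$y
        tv <- pmax(tv, eps0 / 2)   # lowess can dip below zero
    } else {
        tv <- rep(mean(v_bio_raw[def]) + eps0, length(m))
        if (!any(def)) tv <- rep(eps0, length(m))
    }
    trend <- log(tv)
    w <- (n - 1) / (n - 1 + n0)
    raw <- log(ifelse(def, v_bio_raw, 0) + eps0)
    out <- exp(ifelse(def, w, 0) * raw +
               (1 - ifelse(def, w, 0)) * trend) - eps0
    pmax(out, 0)
}

#' Fit the per-gene, per-condition normal expression model
#'
#' Runs normalization (unless already present), estimates technical
#' variance from the bootstrap tensors, computes per-condition means and
#' raw biological variances from replicates
#' (`v_bio_raw = max(0, var(replicates) - v_tech)`, undefined at
#' `n = 1`), shrinks the biological variances with [shrinkBiological()]
#' (pooling all gene x condition cells), and assembles
#' `se = sqrt((v_tech + v_bio) / n)`.
#'
#' @param x A [SkinExperiment-class] with bootstrap matrices.
#' @param offset Log2 pseudo-count, used if `x` is not yet normalized.
#' @param n0,eps0 Passed to [shrinkBiological()].
#' @return A [ConditionModel-class].
#' @examples
#' mdl <- exampleModel(n_genes = 40)
#' condMeans(mdl)[1:2, 1:3]
#' @export
fitConditionModel <- function(x, offset = .DEFAULT_OFFSET, n0 = 3,
                              eps0 = 0.01) {
    stopifnot(is(x, "SkinExperiment"))
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
        x <- normalizeCounts(x, offset = offset)
    logc <- SummarizedExperiment::assay(x, "logcounts")
    vt <- technicalVariance(x)
    sheet <- sampleSheet(x)
    lab <- .conditionLabel(sheet$tissue, sheet$timepoint)
    condLabs <- colnames(vt)
    ng <- nrow(x)
    m <- vraw <- matrix(NA_real_, ng, length(condLabs),
                        dimnames = list(rownames(x), condLabs))
    nrep <- integer(length(condLabs))
    for (k in seq_along(condLabs)) {
        cols <- sheet$sample_id[lab == condLabs[k]]
        if (!length(cols))
            stop("condition absent from data: ", condLabs[k])
        sub <- logc[, cols, drop = FALSE]
        nrep[k] <- length(cols)
        m[, k] <- rowMeans(sub)
        if (nrep[k] >= 2L) {
            s2 <- apply(sub, 1L, var)
            vraw[, k] <- pmax(0, s2 - vt[, k])
        }
    }
    nmat <- matrix(rep(nrep, each = ng), ng)
    vb <- matrix(shrinkBiological(as.vector(vraw), as.vector(m),
                                  as.vector(nmat), n0 = n0, eps0 = eps0),
                 ng, dimnames = dimnames(m))
    se <- sqrt((vt + vb) / nmat)
    ci <- validConditions()
    ci <- ci[match(condLabs, ci$label), , drop = FALSE]
    rownames(ci) <- NULL
    .ConditionModel(means = m, techVar = vt, bioVarRaw = vraw,
                    bioVar = vb, se = se, nrep = as.integer(nrep),
                    conditions = ci,
                    sizeFactors = SummarizedExperiment::colData(x)$sizeFactor,
                    offset = S4Vectors::metadata(x)$offset)
}
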