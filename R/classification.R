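# Fold-change-threshold ordering probabilities and per-timepoint category /
# cross-timepoint flow assignment.

#' Thresholds for the category rules
#'
#' @param theta Log2 fold-change threshold defining "significantly
#'   higher/different"; default `log2(1.5)`.
#' @param epsilon Negligibility probability: an event with probability
#'   `>= epsilon` is "non-negligible" (default 0.02).
#' @param mc_draws Monte Carlo draws used by the sampling oracle
#'   [mcOracleClassify()] (default 1e5).
#' @param seed Seed for the sampling oracle.
#' @return A list of class `flowThresholds`.
#' @examples
#' flowThresholds()
#' @export
flowThresholds <- function(theta = log2(1.5), epsilon = 0.02,
                           mc_draws = 1e5, seed = 1L) {
    stopifnot(theta > 0, epsilon > 0, epsilon < 0.5, mc_draws >= 1)
    structure(list(theta = theta, epsilon = epsilon,
                   mc_draws = as.integer(mc_draws),
                   seed = as.integer(seed)),
              class = "flowThresholds")
}

#' Probability that one condition exceeds another by a threshold
#'
#' Under the normal condition models, `P(mu_A - mu_B > theta)` equals
#' `1 - pnorm((theta - (mA - mB)) / sqrt(seA^2 + seB^2))`. With both
#' standard errors zero the answer degenerates to the indicator of
#' `mA - mB > theta`.
#'
#' @param mA,mB Condition means (vectors recycle).
#' @param seA,seB Standard errors of the condition means (`>= 0`).
#' @param theta Log2 threshold; use 0 for "A more likely highest".
#' @return Probability vector.
#' @examples
#' probExceeds(1.585, 0.5, 0, 0.5, theta = log2(1.5))
#' @export
probExceeds <- function(mA, seA, mB, seB, theta = log2(1.5)) {
    if (any(seA < 0) || any(seB < 0))
        stop("standard errors must be non-negative")
    d <- mA - mB
    s <- sqrt(seA^2 + seB^2)
    out <- ifelse(s > 0, pnorm((theta - d) / s, lower.tail = FALSE),
                  as.numeric(d > theta))
    unname(out)
}

# Deterministic bivariate-normal lower orthant P(Z1 <= a, Z2 <= b) with
# positive-semidefinite 2x2 covariance; degenerate margins collapse to
# indicators/univariate terms.
.orthant2 <- function(a, b, mean1, mean2, var1, var2, cov12) {
    p1 <- if (var1 > 0) pnorm(a, mean1, sqrt(var1)) else
        as.numeric(mean1 <= a)
    p2 <- if (var2 > 0) pnorm(b, mean2, sqrt(var2)) else
        as.numeric(mean2 <= b)
    if (var1 <= 0 || var2 <= 0 || cov12 <= 0)
        return(p1 * p2)
    rho <- cov12 / sqrt(var1 * var2)
    if (rho >= 1 - 1e-12)   # comonotone limit
        return(min(p1, p2))
    sig <- matrix(c(var1, cov12, cov12, var2), 2L)
    as.numeric(mvtnorm::pmvnorm(upper = c(a, b), mean = c(mean1, mean2),
                                sigma = sig,
                                algorithm = mvtnorm::Miwa(steps = 512)))
}

#' Probability that neither skin layer exceeds the nonskin reference
#'
#' The event that neither periderm nor basal is significantly higher
#' than the nonskin reference:
#' `P(mu_P - mu_N <= theta and mu_B - mu_N <= theta)`. The two
#' differences share the reference mean, so they are positively
#' correlated: `Var(D_i) = se_i^2 + seN^2`, `Cov(D_1, D_2) = seN^2`. The
#' probability is the exact bivariate-normal orthant (deterministic Miwa
#' quadrature); with `seN = 0` it reduces to the product of the
#' marginals.
#'
#' @param mP,seP,mB,seB,mN,seN Means and standard errors of the
#'   periderm, basal and nonskin condition models.
#' @param theta Log2 fold-change threshold.
#' @return Scalar probability.
#' @examples
#' probNeitherAbove(5, 0.5, 5, 0.5, 5, 0.5)
#' @export
probNeitherAbove <- function(mP, seP, mB, seB, mN, seN,
                             theta = log2(1.5)) {
    if (any(c(seP, seB, seN) < 0))
        stop("standard errors must be non-negative")
    .orthant2(theta, theta, mP - mN, mB - mN,
              seP^2 + seN^2, seB^2 + seN^2, seN^2)
}

#' Probability that the two layers are not significantly different
#'
#' `P(|mu_P - mu_B| <= theta)` under the normal models:
#' `pnorm((theta - d) / s) - pnorm((-theta - d) / s)` with
#' `d = mP - mB`, `s = sqrt(seP^2 + seB^2)`; with `s = 0` the indicator
#' of `|d| <= theta`.
#'
#' @param mP,seP,mB,seB Layer means and standard errors.
#' @param theta Log2 fold-change threshold.
#' @return Probability vector.
#' @examples
#' probNotDifferent(5, 0.3, 5, 0.3)
#' @export
probNotDifferent <- function(mP, seP, mB, seB, theta = log2(1.5)) {
    if (any(seP < 0) || any(seB < 0))
        stop("standard errors must be non-negative")
    d <- mP - mB
    s <- sqrt(seP^2 + seB^2)
    out <- ifelse(s > 0, pnorm((theta - d) / s) - pnorm((-theta - d) / s),
                  as.numeric(abs(d) <= theta))
    unname(out)
}

.modelRow <- function(model, tissue, timepoint) {
    lab <- .conditionLabel(tissue, timepoint)
    k <- match(lab, model@conditions$label)
    if (is.na(k))
        stop("condition missing from model: ", lab)
    list(m = model@means[, k], se = model@se[, k])
}

#' Classify genes at the 20-somite stage
#'
#' A gene is a skin gene (`S`) when it is significantly higher in
#' `all_skin` than in `nonskin1` at the fold-change threshold: the
#' probability of *not* being higher,
#' `P(mu_allskin - mu_nonskin1 <= theta)`, must be negligible
#' (`< epsilon`). Otherwise the gene is nonskin (`N`).
#'
#' @param model A [ConditionModel-class] containing `all_skin.20SS` and
#'   `nonskin1.20SS`.
#' @param th A [flowThresholds()].
#' @return Character vector (`"S"`/`"N"`) named by gene.
#' @examples
#' table(classify20SS(exampleModel(n_genes = 40)))
#' @export
classify20SS <- function(model, th = flowThresholds()) {
    A <- .modelRow(model, "all_skin", "20SS")
    N <- .modelRow(model, "nonskin1", "20SS")
    pNotHigher <- 1 - probExceeds(A$m, A$se, N$m, N$se, th$theta)
    setNames(ifelse(pNotHigher < th$epsilon, "S", "N"),
             rownames(model@means))
}

#' Classify genes at 52 or 72 hpf
#'
#' Decision cascade over ordering probabilities of periderm (P), basal
#' (B) and the nonskin reference (N2): a non-negligible probability
#' (`>= epsilon`) that neither layer is significantly higher than the
#' reference gives `N`; otherwise a non-negligible probability that the
#' layers are not significantly different gives `G`; otherwise the gene
#' is `P` or `B` according to which layer is more likely highest
#' (`P(mu_P > mu_B)` vs 0.5; an exact tie goes to `B`).
#'
#' @param model A [ConditionModel-class].
#' @param timepoint `"52hpf"` or `"72hpf"`.
#' @param th A [flowThresholds()].
#' @return Character vector over `{N, G, B, P}` named by gene.
#' @examples
#' table(classifyLater(exampleModel(n_genes = 40), "52hpf"))
#' @export
classifyLater <- function(model, timepoint, th = flowThresholds()) {
    stopifnot(timepoint %in% c("52hpf", "72hpf"))
    P <- .modelRow(model, "periderm", timepoint)
    B <- .modelRow(model, "basal", timepoint)
    N <- .modelRow(model, "nonskin2", timepoint)
    ng <- length(P$m)
    out <- character(ng)
    pND <- probNotDifferent(P$m, P$se, B$m, B$se, th$theta)
    pPhi <- probExceeds(P$m, P$se, B$m, B$se, theta = 0)
    for (i in seq_len(ng)) {
        pNA <- probNeitherAbove(P$m[i], P$se[i], B$m[i], B$se[i],
                                N$m[i], N$se[i], th$theta)
        out[i] <- if (pNA >= th$epsilon) "N"
        else if (pND[i] >= th$epsilon) "G"
        else if (pPhi[i] > 0.5) "P" else "B"
    }
    setNames(out, rownames(model@means))
}

#' Assemble per-timepoint categories into flows
#'
#' @param cat20,cat52,cat72 Category vectors from [classify20SS()] and
#'   [classifyLater()] (equal length; names preserved from `cat20`).
#' @return data.frame with columns `gene`, `cat20SS`, `cat52hpf`,
#'   `cat72hpf`, `flow` (the three characters concatenated in timepoint
#'   order).
#' @examples
#' assignFlows(c(g1 = "S"), c(g1 = "P"), c(g1 = "P"))$flow
#' @export
assignFlows <- function(cat20, cat52, cat72) {
    stopifnot(length(cat20) == length(cat52),
              length(cat52) == length(cat72),
              all(cat20 %in% .CATS_20SS),
              all(cat52 %in% .CATS_LATER),
              all(cat72 %in% .CATS_LATER))
    genes <- names(cat20)
    if (is.null(genes)) genes <- sprintf("gene%d", seq_along(cat20))
    data.frame(gene = genes, cat20SS = unname(cat20),
               cat52hpf = unname(cat52), cat72hpf = unname(cat72),
               flow = paste0(cat20, cat52, cat72),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify all genes and assign flows
#'
#' Convenience driver: [classify20SS()] + [classifyLater()] at both
#' later timepoints + [assignFlows()].
#'
#' @param model A [ConditionModel-class] over the full 12-condition
#'   design.
#' @param th A [flowThresholds()].
#' @return data.frame as from [assignFlows()].
#' @examples
#' head(classifyFlows(exampleModel(n_genes = 40)))
#' @export
classifyFlows <- function(model, th = flowThresholds()) {
    assignFlows(classify20SS(model, th),
                classifyLater(model, "52hpf", th),
                classifyLater(model, "72hpf", th))
}

#' Expand a flow query pattern into concrete flows
#'
#' Patterns are three characters: position 1 over `{N, S, *}`, positions
#' 2-3 over `{N, G, B, P, S, *}`. `*` means any category at that
#' timepoint; `S` at positions 2-3 means "any skin category"
#' (`{G, B, P}`).
#'
#' @param q Pattern string.
#' @return Character vector of concrete flow labels.
#' @examples
#' expandFlowQuery("*BB")
#' length(expandFlowQuery("SSS"))   # 9
#' @export
expandFlowQuery <- function(q) {
    stopifnot(is.character(q), length(q) == 1L)
    if (nchar(q) != 3L)
        stop("flow query must have exactly 3 characters")
    ch <- strsplit(q, "")[[1L]]
    expand1 <- function(c, pos) {
        if (pos == 1L) {
            switch(c, "*" = .CATS_20SS, "N" = "N", "S" = "S",
                   stop("invalid character '", c,
                        "' at position 1 of flow query"))
        } else {
            switch(c, "*" = .CATS_LATER, "S" = c("G", "B", "P"),
                   "N" = "N", "G" = "G", "B" = "B", "P" = "P",
                   stop("invalid character '", c, "' at position ", pos,
                        " of flow query"))
        }
    }
    g <- expand.grid(a = expand1(ch[1L], 1L), b = expand1(ch[2L], 2L),
                     c = expand1(ch[3L], 3L), stringsAsFactors = FALSE)
    sort(paste0(g$a, g$b, g$c))
}

#' Count genes matching flow query patterns
#'
#' @param calls data.frame from [classifyFlows()] (needs a `flow`
#'   column).
#' @param queries Character vector of flow patterns (see
#'   [expandFlowQuery()]).
#' @return data.frame with columns `query` and `count`.
#' @examples
#' calls <- classifyFlows(exampleModel(n_genes = 40))
#' flowCounts(calls, c("***", "*BB", "SSS"))
#' @export
flowCounts <- function(calls, queries) {
    stopifnot("flow" %in% colnames(calls))
    counts <- vapply(queries, function(q)
        sum(calls$flow %in% expandFlowQuery(q)), 0L)
    data.frame(query = queries, count = unname(counts),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Monte Carlo oracle for the later-timepoint classification
#'
#' Draws `mc_draws` joint samples of the three condition means from
#' independent normals, estimates the three event probabilities
#' empirically, and applies the same decision cascade as
#' [classifyLater()]. Used as an independent check of the analytic
#' probabilities (which model the shared-reference correlation exactly);
#' the two agree except for genes whose analytic probabilities lie
#' within Monte Carlo error of `epsilon`.
#'
#' @param model A [ConditionModel-class].
#' @param timepoint `"52hpf"` or `"72hpf"`.
#' @param th A [flowThresholds()]; `mc_draws` and `seed` control the
#'   sampling.
#' @return Character vector over `{N, G, B, P}` named by gene.
#' @examples
#' mdl <- exampleModel(n_genes = 20)
#' th <- flowThresholds(mc_draws = 2e4, seed = 5)
#' mean(mcOracleClassify(mdl, "52hpf", th) ==
#'      classifyLater(mdl, "52hpf", th))
#' @export
mcOracleClassify <- function(model, timepoint, th = flowThresholds()) {
    stopifnot(timepoint %in% c("52hpf", "72hpf"))
    P <- .modelRow(model, "periderm", timepoint)
    B <- .modelRow(model, "basal", timepoint)
    N <- .modelRow(model, "nonskin2", timepoint)
    set.seed(th$seed)
    ng <- length(P$m)
    out <- character(ng)
    for (i in seq_len(ng)) {
        muP <- rnorm(th$mc_draws, P$m[i], P$se[i])
        muB <- rnorm(th$mc_draws, B$m[i], B$se[i])
        muN <- rnorm(th$mc_draws, N$m[i], N$se[i])
        pNA <- mean(muP - muN <= th$theta & muB - muN <= th$theta)
        pND <- mean(abs(muP - muB) <= th$theta)
        pPhi <- mean(muP - muB > 0)
        out[i] <- if (pNA >= th$epsilon) "N"
        else if (pND >= th$epsilon) "G"
        else if (pPhi > 0.5) "P" else "B"
    }
    setNames(out, rownames(model@means))
}
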