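# Synthetic-data generator emulating the 12-condition, 23-sample sorted-cell
# design: ground-truth flows -> condition means -> log-normal replicate noise
# -> multinomial bootstrap tensors.

.DEFAULT_THETA <- log2(1.5)

# Default flow mix: mostly nonskin genes, skin-enriched mass spread over
# stable and transitioning flows; the four basal<->periderm exchange flows
# (SBP, SPB, NBP, NPB) carry zero mass, as observed in sorted-cell data.
.defaultTruthMix <- function() {
    c(NNN = 0.70, SPP = 0.03, SBB = 0.03, SGG = 0.05, NGG = 0.04,
      NPP = 0.02, NBB = 0.02, SNN = 0.03, NGN = 0.02, NNG = 0.02,
      SGN = 0.01, NPN = 0.01, NBN = 0.01, NNP = 0.005, NNB = 0.005)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults reproduce the study design: 12 (tissue, timepoint) conditions
#' with two biological replicates each except a single replicate of
#' `nonskin2` at 52 hpf (23 samples), and 1,000 bootstrap count vectors
#' per sample. `dispersion` is the biological standard deviation on the
#' log2 scale; `effect_size` is the log2 separation between "higher" and
#' "lower" tissues in the truth, defaulting to four times the
#' fold-change threshold theta = log2(1.5) so that true categories are
#' unambiguous.
#'
#' @param n_genes Number of genes.
#' @param conditions data.frame of (tissue, timepoint) pairs; default
#'   [validConditions()].
#' @param replicates_per_condition Named integer vector (condition label
#'   -> replicate count); default two everywhere except
#'   `nonskin2.52hpf = 1`.
#' @param n_bootstraps Bootstrap vectors per sample (B >= 2).
#' @param dispersion Biological log2-scale standard deviation.
#' @param library_size_range Range the per-sample library scaling factor
#'   is drawn from (uniform).
#' @param seed Integer seed; the same configuration and seed give
#'   bit-identical output.
#' @param truth_mix Named numeric vector of flow-label proportions
#'   (must sum to 1).
#' @param effect_size Log2 separation between higher and lower tissues.
#' @param assay_noise Draw each sample's observed counts as one
#'   multinomial realization of its expected abundances (default TRUE).
#'   Quantifier point estimates carry assay noise that their bootstrap
#'   spread quantifies; without this step replicate variance would
#'   underestimate `dispersion^2 + v_tech` and the model's
#'   technical-variance subtraction would be biased.
#'
#' @return A list of class `simConfig`.
#' @examples
#' cfg <- simConfig(n_genes = 100, seed = 7)
#' cfg$effect_size / log2(1.5)   # 4 theta by default
#' @export
simConfig <- function(n_genes = 2000L,
                      conditions = validConditions(),
                      replicates_per_condition = NULL,
                      n_bootstraps = 1000L,
                      dispersion = 0.25,
                      library_size_range = c(0.7, 1.4),
                      seed = 1L,
                      truth_mix = .defaultTruthMix(),
                      effect_size = 4 * .DEFAULT_THETA,
                      assay_noise = TRUE) {
    if (is.null(replicates_per_condition)) {
        replicates_per_condition <- setNames(
            rep(2L, nrow(conditions)), conditions$label)
        if ("nonskin2.52hpf" %in% names(replicates_per_condition))
            replicates_per_condition[["nonskin2.52hpf"]] <- 1L
    }
    stopifnot(n_genes >= 1, n_bootstraps >= 2, dispersion >= 0,
              effect_size > 0, length(library_size_range) == 2L,
              all(library_size_range > 0),
              all(conditions$label %in% validConditions()$label),
              all(names(replicates_per_condition) %in% conditions$label),
              all(replicates_per_condition >= 1L))
    .checkFlowLabel(names(truth_mix))
    if (abs(sum(truth_mix) - 1) > 1e-8)
        stop("truth_mix proportions must sum to 1")
    structure(list(n_genes = as.integer(n_genes), conditions = conditions,
                   replicates_per_condition = replicates_per_condition,
                   n_bootstraps = as.integer(n_bootstraps),
                   dispersion = dispersion,
                   library_size_range = library_size_range,
                   seed = as.integer(seed), truth_mix = truth_mix,
                   effect_size = effect_size,
                   assay_noise = isTRUE(assay_noise)),
              class = "simConfig")
}

#' Generate ground-truth expression programs
#'
#' Assigns each gene a flow label drawn from `truth_mix` and constructs
#' per-condition true log2 means so that noise-free classification (zero
#' standard errors) reproduces the assigned flow exactly: at 20 SS an `S`
#' gene has `all_skin` above `nonskin1` by `effect_size`; at 52/72 hpf a
#' `P` (`B`) gene has periderm (basal) above the other layer and the
#' nonskin reference by `effect_size`, a `G` gene has both layers equally
#' above the reference, and an `N` gene has all three equal. The
#' `all_skin` mean at the later timepoints is the log2 of the linear-scale
#' average of the two layer means; `nonskin1` tracks `nonskin2`.
#'
#' @param config A [simConfig()].
#' @return A list of class `truthTable` with elements `means` (genes x
#'   conditions matrix of true log2 means), `flows` (per-gene label) and
#'   `categories` (genes x 3 character matrix).
#' @examples
#' tt <- generateTruth(simConfig(n_genes = 10, seed = 1))
#' table(tt$flows)
#' @export
generateTruth <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    mix <- config$truth_mix
    .checkFlowLabel(names(mix))
    n <- config$n_genes
    flows <- sample(names(mix), n, replace = TRUE, prob = mix)
    genes <- sprintf("gene%05d", seq_len(n))
    base <- runif(n, min = 5, max = 9)  # log2 baseline abundance
    eff <- config$effect_size
    conds <- validConditions()
    means <- matrix(NA_real_, n, nrow(conds),
                    dimnames = list(genes, conds$label))
    cat20 <- substr(flows, 1L, 1L)
    catL <- cbind(`52hpf` = substr(flows, 2L, 2L),
                  `72hpf` = substr(flows, 3L, 3L))
    means[, "nonskin1.20SS"] <- base
    means[, "all_skin.20SS"] <- base + ifelse(cat20 == "S", eff, 0)
    for (tp in c("52hpf", "72hpf")) {
        cc <- catL[, tp]
        peri <- base + ifelse(cc %in% c("P", "G"), eff, 0)
        basal <- base + ifelse(cc %in% c("B", "G"), eff, 0)
        nons <- base
        means[, .conditionLabel("periderm", tp)] <- peri
        means[, .conditionLabel("basal", tp)] <- basal
        means[, .conditionLabel("nonskin2", tp)] <- nons
        means[, .conditionLabel("all_skin", tp)] <-
            log2((2^peri + 2^basal) / 2)
        means[, .conditionLabel("nonskin1", tp)] <- nons
    }
    keep <- conds$label %in% config$conditions$label
    categories <- cbind(`20SS` = cat20, catL)
    rownames(categories) <- genes
    structure(list(means = means[, keep, drop = FALSE], flows = flows,
                   categories = categories),
              class = "truthTable")
}

#' Simulate counts and bootstrap tensors from a truth table
#'
#' Per-sample expected abundances are
#' `2^(true log2 mean + Normal(0, dispersion^2))`, scaled by a library
#' factor drawn uniformly from `library_size_range`; with
#' `assay_noise = TRUE` (default) the observed counts are one
#' multinomial draw of the rounded abundance total, emulating the assay
#' noise of quantifier point estimates. Each sample's bootstrap matrix
#' then resamples the sample's total count multinomially with
#' probabilities proportional to the observed counts, so every bootstrap
#' column conserves the total and the bootstrap mean approximates the
#' observed counts — the structure quantifier Gibbs resamples exhibit.
#'
#' @param truth A `truthTable` from [generateTruth()].
#' @param config The same [simConfig()] used to build the truth.
#' @return A [SkinExperiment-class] with assay `"counts"`, per-sample
#'   bootstrap matrices, and the truth stored in
#'   `S4Vectors::metadata(x)$truth`.
#' @examples
#' cfg <- simConfig(n_genes = 30, n_bootstraps = 10, seed = 2)
#' sim <- simulateCounts(generateTruth(cfg), cfg)
#' dim(sim)
#' @export
simulateCounts <- function(truth, config) {
    stopifnot(inherits(truth, "truthTable"),
              inherits(config, "simConfig"))
    set.seed(config$seed + 1L)
    conds <- config$conditions
    reps <- config$replicates_per_condition
    rows <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
        lab <- conds$label[i]
        r <- if (lab %in% names(reps)) reps[[lab]] else 2L
        data.frame(tissue = conds$tissue[i], timepoint = conds$timepoint[i],
                   replicate = seq_len(r), stringsAsFactors = FALSE)
    }))
    rows$sample_id <- sprintf("%s.%s.rep%d", rows$tissue, rows$timepoint,
                              rows$replicate)
    genes <- rownames(truth$means)
    ns <- nrow(rows)
    libf <- runif(ns, config$library_size_range[1L],
                  config$library_size_range[2L])
    counts <- matrix(0, length(genes), ns,
                     dimnames = list(genes, rows$sample_id))
    for (j in seq_len(ns)) {
        mu <- truth$means[, .conditionLabel(rows$tissue[j],
                                            rows$timepoint[j])]
        noise <- if (config$dispersion > 0)
            rnorm(length(mu), 0, config$dispersion) else 0
        lambda <- 2^(mu + noise) * libf[j]
        counts[, j] <- if (config$assay_noise) {
            # one multinomial draw: the observed counts carry the assay
            # noise their bootstrap resamples quantify
            drop(rmultinom(1L, size = round(sum(lambda)), prob = lambda))
        } else lambda
    }
    boots <- lapply(seq_len(ns), function(j) {
        tot <- round(sum(counts[, j]))
        b <- rmultinom(config$n_bootstraps, size = tot,
                       prob = counts[, j])
        storage.mode(b) <- "double"
        rownames(b) <- genes
        b
    })
    names(boots) <- rows$sample_id
    se <- SkinExperiment(counts, rows[, c("sample_id", "tissue",
                                          "timepoint", "replicate")],
                         bootstraps = boots)
    S4Vectors::metadata(se)$truth <- truth
    S4Vectors::metadata(se)$config <- config
    se
}

#' A small fitted example model
#'
#' Convenience for examples and interactive exploration: simulates a
#' compact dataset under the default design and fits the condition model.
#'
#' @param n_genes,n_bootstraps,seed Passed to [simConfig()].
#' @return A [ConditionModel-class].
#' @examples
#' exampleModel(n_genes = 40)
#' @export
exampleModel <- function(n_genes = 60L, n_bootstraps = 30L, seed = 11L) {
    cfg <- simConfig(n_genes = n_genes, n_bootstraps = n_bootstraps,
                     seed = seed)
    sim <- simulateCounts(generateTruth(cfg), cfg)
    fitConditionModel(sim)
}
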