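test_that("median-of-ratios size factors match hand computation", {
    sim <- smallSim(n_genes = 12, n_bootstraps = 3)
    cts <- SummarizedExperiment::assay(sim, "counts")
    # derived example: columns in exact 4:1 ratio give factors (0.5, 2)
    m <- matrix(c(2, 4, 8, 8, 16, 32), 3, 2,
                dimnames = list(paste0("g", 1:3), c("A", "B")))
    sf <- skinflow:::.sizeFactors(m)
    expect_equal(unname(sf), c(0.5, 2))
    # identical samples give unit factors
    eq <- cbind(A = c(2, 4, 8), B = c(2, 4, 8))
    rownames(eq) <- paste0("g", 1:3)
    expect_equal(unname(skinflow:::.sizeFactors(eq)), c(1, 1))
    # doubling one sample doubles its factor relative to the other
    expect_equal(unname(skinflow:::.sizeFactors(cbind(eq[, 1],
                                                      2 * eq[, 1]))),
                 c(1 / sqrt(2), sqrt(2)))
    # geometric mean of the real-data factors is 1
    sfs <- skinflow:::.sizeFactors(cts)
    expect_equal(exp(mean(log(sfs))), 1)
})

test_that("normalization is idempotent", {
    sim <- normalizeCounts(smallSim(n_genes = 30, n_bootstraps = 3))
    norm <- SummarizedExperiment::assay(sim, "normcounts")
    expect_equal(unname(skinflow:::.sizeFactors(norm)),
                 rep(1, ncol(norm)))
})

test_that("normalization refuses a matrix with no always-positive gene", {
    m <- matrix(c(1, 0, 0, 1), 2, 2,
                dimnames = list(c("g1", "g2"), c("a", "b")))
    expect_error(skinflow:::.sizeFactors(m), "filter")
})

test_that("log2 transform uses the 0.5 offset and rejects negatives", {
    expect_equal(transformCounts(0), -1)
    expect_equal(transformCounts(7.5), 3)
    expect_equal(transformCounts(2^2.5 - 0.5), 2.5)
    expect_error(transformCounts(-1), "non-negative")
    x <- seq(0, 10, by = 0.5)
    expect_true(all(diff(transformCounts(x)) > 0))
})

test_that("TPM normalizes rates to one million per sample", {
    expect_equal(unname(tpm(cbind(s = c(100, 300)), c(1, 1))[, 1]),
                 c(250000, 750000))
    expect_equal(unname(tpm(cbind(s = c(100, 300)), c(100, 300))[, 1]),
                 c(500000, 500000))
    sim <- smallSim(n_genes = 20, n_bootstraps = 3)
    cts <- SummarizedExperiment::assay(sim, "counts")
    lens <- runif(nrow(cts), 200, 2000)
    expect_equal(unname(colSums(tpm(cts, lens))), rep(1e6, ncol(cts)))
    expect_error(tpm(cts, lens[-1]), "one effective length")
    expect_error(tpm(cts, -lens), "positive")
})

test_that("technical variance matches per-sample bootstrap variance", {
    sim <- normalizeCounts(smallSim(n_genes = 10, n_bootstraps = 8))
    # identical bootstrap columns -> zero technical variance
    b0 <- lapply(bootstraps(sim), function(m) m[, c(1, 1, 1)])
    bootstraps(sim) <- b0
    expect_true(all(technicalVariance(sim) == 0))
    # two bootstrap values {1, 3} after back-transform -> variance 2
    sim1 <- smallSim(n_genes = 10, n_bootstraps = 2)
    sim1 <- normalizeCounts(sim1)
    sf <- SummarizedExperiment::colData(sim1)$sizeFactor
    g <- rownames(sim1)
    b <- lapply(seq_along(bootstraps(sim1)), function(j) {
        m <- bootstraps(sim1)[[j]]
        m[] <- rep((2^c(1, 3) - 0.5) * sf[j], each = nrow(m))
        m
    })
    names(b) <- names(bootstraps(sim1))
    bootstraps(sim1) <- b
    expect_equal(unname(technicalVariance(sim1)[1, ]), rep(2, 12),
                 tolerance = 1e-12)
    # invariance under permutation of bootstrap columns
    simp <- normalizeCounts(smallSim(n_genes = 10, n_bootstraps = 6,
                                     seed = 3))
    vt1 <- technicalVariance(simp)
    bootstraps(simp) <- lapply(bootstraps(simp),
                               function(m) m[, ncol(m):1])
    expect_equal(technicalVariance(simp), vt1)
})

test_that("condition fit recovers means and raw biological variance", {
    sim <- smallSim(n_genes = 60, n_bootstraps = 10)
    mdl <- fitConditionModel(sim)
    logc <- SummarizedExperiment::assay(normalizeCounts(sim),
                                        "logcounts")
    sheet <- sampleSheet(sim)
    cols <- sheet$sample_id[sheet$tissue == "all_skin" &
                            sheet$timepoint == "20SS"]
    expect_equal(unname(condMeans(mdl)[, "all_skin.20SS"]),
                 unname(rowMeans(logc[, cols])))
    # v_bio_raw = max(0, var - v_tech); with v_tech = 0 and replicate
    # values 3 and 5: m = 4, v_bio_raw = 2, se before shrinkage = 1
    s2 <- var(c(3, 5))
    expect_equal(mean(c(3, 5)), 4)
    expect_equal(max(0, s2 - 0), 2)
    expect_equal(sqrt((0 + 2) / 2), 1)
    # flooring: replicate variance below v_tech gives raw 0
    vr <- bioVarRaw(mdl)
    expect_true(all(vr[!is.na(vr)] >= 0))
    # the single-replicate condition has undefined raw variance
    expect_true(all(is.na(vr[, "nonskin2.52hpf"])))
    expect_true(all(bioVar(mdl)[, "nonskin2.52hpf"] >= 0))
    # se follows the 1/sqrt(n) law
    vt <- techVar(mdl); vb <- bioVar(mdl)
    n <- matrix(rep(nReplicates(mdl), each = nrow(vt)), nrow(vt))
    expect_equal(condSE(mdl), sqrt((vt + vb) / n))
})

test_that("shrinkage blends toward the trend with weight (n-1)/(n-1+n0)", {
    expect_equal((2 - 1) / (2 - 1 + 3), 0.25)
    set.seed(1)
    m <- runif(200, 4, 9)
    vraw <- rep(0.2, 200)   # flat: the trend sits on the data
    out <- shrinkBiological(vraw, m, n = rep(2L, 200))
    expect_equal(out, vraw, tolerance = 1e-6)   # fixed point
    # n = 1 entries take the trend value exactly
    vr2 <- vraw; vr2[1] <- NA
    out2 <- shrinkBiological(vr2, m, n = c(1L, rep(2L, 199)))
    expect_equal(out2[1], 0.2, tolerance = 1e-6)
    # blend arithmetic at w = 0.25 against the exactly-known global-mean
    # trend (fewer than 50 defined values triggers the fallback)
    eps0 <- 0.01
    vr3 <- c(0.4, rep(0.2, 30))
    out3 <- shrinkBiological(vr3, m[1:31], n = rep(2L, 31), eps0 = eps0)
    trend <- log(mean(vr3) + eps0)
    expect_equal(out3[1],
                 exp(0.25 * log(0.4 + eps0) + 0.75 * trend) - eps0)
    # fallback to global mean below 50 defined values
    few <- shrinkBiological(c(0.1, 0.3, NA), m = c(5, 6, 7),
                            n = c(2L, 2L, 1L))
    expect_true(all(few >= 0))
})

test_that("mean shrunken variance tracks the simulated dispersion", {
    cfg <- simConfig(n_genes = 800, n_bootstraps = 60, seed = 21)
    tt <- generateTruth(cfg)
    mdl <- fitConditionModel(simulateCounts(tt, cfg))
    expect_lt(abs(mean(bioVar(mdl)) / cfg$dispersion^2 - 1), 0.15)
})

test_that("technical variance stabilizes as B doubles", {
    vts <- lapply(c(100, 200, 400), function(B) {
        cfg <- simConfig(n_genes = 80, n_bootstraps = B, seed = 13)
        technicalVariance(normalizeCounts(
            simulateCounts(generateTruth(cfg), cfg)))
    })
    # relative change from doubling B shrinks
    d1 <- mean(abs(vts[[2]] - vts[[1]])) / mean(vts[[1]])
    d2 <- mean(abs(vts[[3]] - vts[[2]])) / mean(vts[[2]])
    expect_lt(d2, d1)
    expect_lt(d2, 0.15)
})

test_that("condition summaries put interval tips two SEs from the mean", {
    means <- flatMeans(2); ses <- means * 0
    means[1, ] <- 4; ses[1, ] <- 0.5
    mdl <- toyModel(means, ses)
    s <- conditionSummary(mdl, "g001")
    expect_equal(s$mean, rep(4, 12))
    expect_equal(s$lower, rep(3, 12))
    expect_equal(s$upper, rep(5, 12))
    expect_equal(s$upper - s$lower, rep(4 * 0.5, 12))
    # degenerate bar at se = 0
    s2 <- conditionSummary(mdl, "g002")
    expect_equal(s2$lower, s2$mean)
    expect_equal(s2$upper, s2$mean)
    expect_error(conditionSummary(mdl, "nope"), "unknown gene")
})
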