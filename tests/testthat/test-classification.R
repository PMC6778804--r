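theta <- log2(1.5)

test_that("exceedance probability matches frozen normal-CDF values", {
    # (theta - d)/s = (0.585 - 1.585)/sqrt(0.5) = -1.41421 -> 0.92135
    expect_equal(probExceeds(1.585, 0.5, 0, 0.5, theta = 0.585),
                 0.92135, tolerance = 1e-4)
    # symmetry: d = theta gives exactly 1/2
    expect_equal(probExceeds(5 + theta, 0.3, 5, 0.4, theta), 0.5)
    # degenerate SEs give the indicator
    expect_equal(probExceeds(2 * 0.585, 0, 0, 0, theta = 0.585), 1)
    expect_equal(probExceeds(0.5, 0, 0, 0, theta = 0.585), 0)
})

test_that("not-different probability matches frozen normal-CDF values", {
    # Phi(-1.17) - Phi(-3.51) = 0.12078
    expect_equal(probNotDifferent(1.17, 0.3, 0, 0.4, theta = 0.585),
                 0.12078, tolerance = 1e-4)
    # symmetric interval at equal means
    s <- sqrt(0.3^2 + 0.4^2)
    expect_equal(probNotDifferent(5, 0.3, 5, 0.4, theta),
                 2 * pnorm(theta / s) - 1)
    # degenerate: |d| < theta with zero spread is certain
    expect_equal(probNotDifferent(5.1, 0, 5, 0, theta), 1)
    expect_equal(probNotDifferent(7, 0, 5, 0, theta), 0)
})

test_that("neither-above probability handles the shared reference", {
    # seN = 0 decouples the two events into a product of marginals
    p <- probNeitherAbove(5, 0.3, 5.2, 0.4, 4.8, 0, theta)
    expect_equal(p, (1 - probExceeds(5, 0.3, 4.8, 0, theta)) *
                    (1 - probExceeds(5.2, 0.4, 4.8, 0, theta)),
                 tolerance = 1e-12)
    # both layers far above the reference: essentially zero
    expect_lt(probNeitherAbove(15, 0.1, 15, 0.1, 5, 0.1, theta), 1e-15)
    # all equal with generous spread: comfortably non-negligible
    expect_gt(probNeitherAbove(5, 0.5, 5, 0.5, 5, 0.5, theta), 0.5)
})

test_that("analytic orthant agrees with a large Monte Carlo estimate", {
    set.seed(404)
    draws <- 1e6
    for (case in list(c(mP = 5, seP = 0.5, mB = 5, seB = 0.5,
                        mN = 5, seN = 0.5),
                      c(5.8, 0.3, 5.2, 0.6, 5.0, 0.4),
                      c(4.9, 0.2, 5.6, 0.2, 5.1, 0.3))) {
        muP <- rnorm(draws, case[1], case[2])
        muB <- rnorm(draws, case[3], case[4])
        muN <- rnorm(draws, case[5], case[6])
        emp <- mean(muP - muN <= theta & muB - muN <= theta)
        ana <- probNeitherAbove(case[1], case[2], case[3], case[4],
                                case[5], case[6], theta)
        se <- sqrt(emp * (1 - emp) / draws)
        expect_lt(abs(ana - emp), 3 * se + 1e-12)
    }
})

test_that("translation invariance: only differences matter", {
    set.seed(7)
    for (i in 1:20) {
        m <- runif(3, 3, 8); s <- runif(3, 0.05, 0.6)
        shift <- runif(1, -5, 5)
        p1 <- probNeitherAbove(m[1], s[1], m[2], s[2], m[3], s[3], theta)
        p2 <- probNeitherAbove(m[1] + shift, s[1], m[2] + shift, s[2],
                               m[3] + shift, s[3], theta)
        expect_equal(p1, p2, tolerance = 1e-9)
        expect_equal(probNotDifferent(m[1], s[1], m[2], s[2], theta),
                     probNotDifferent(m[1] + shift, s[1],
                                      m[2] + shift, s[2], theta))
    }
})

test_that("20SS rule calls S only for clearly higher all-skin", {
    means <- flatMeans(3); ses <- means * 0 + 0.2
    means[1, "all_skin.20SS"] <- means[1, "nonskin1.20SS"] + 10 * theta
    means[2, "all_skin.20SS"] <- means[2, "nonskin1.20SS"]          # equal
    means[3, "all_skin.20SS"] <- means[3, "nonskin1.20SS"] + theta  # at the line
    cats <- classify20SS(toyModel(means, ses))
    expect_equal(unname(cats), c("S", "N", "N"))
})

test_that("later-timepoint cascade assigns N, G, P and B correctly", {
    base <- flatMeans(4); ses <- base * 0
    ses[] <- 0.2
    # g1: all equal -> N ; g2: both layers up -> G ;
    # g3: periderm up -> P ; g4: basal up -> B
    for (tp in c("52hpf", "72hpf")) {
        base[2, paste0(c("periderm.", "basal."), tp)] <- 8
        base[3, paste0("periderm.", tp)] <- 9
        base[4, paste0("basal.", tp)] <- 9
    }
    ses[3, ] <- 0.1; ses[4, ] <- 0.1
    mdl <- toyModel(base, ses)
    expect_equal(unname(classifyLater(mdl, "52hpf")),
                 c("N", "G", "P", "B"))
    expect_equal(unname(classifyLater(mdl, "72hpf")),
                 c("N", "G", "P", "B"))
    flows <- classifyFlows(mdl)
    expect_equal(flows$flow, c("NNN", "NGG", "NPP", "NBB"))
})

test_that("raising the periderm mean never flips P toward B", {
    ses <- flatMeans(1) * 0 + 0.25
    lastCat <- "B"
    for (mP in seq(5, 9, by = 0.25)) {
        means <- flatMeans(1)
        means[1, "periderm.52hpf"] <- mP
        means[1, "basal.52hpf"] <- 6.5
        cat <- unname(classifyLater(toyModel(means, ses), "52hpf"))
        if (cat == "P") lastCat <- "P"
        if (lastCat == "P") expect_equal(cat, "P")
    }
})

test_that("every gene gets exactly one category per timepoint", {
    sim <- smallSim(n_genes = 120, n_bootstraps = 15, seed = 31)
    calls <- classifyFlows(fitConditionModel(sim))
    expect_equal(nrow(calls), 120L)
    expect_true(all(calls$cat20SS %in% c("S", "N")))
    expect_true(all(calls$cat52hpf %in% c("N", "G", "B", "P")))
    counts <- flowCounts(calls, allFlows())
    expect_equal(sum(counts$count), 120L)
})

test_that("flow assembly concatenates categories in timepoint order", {
    expect_equal(assignFlows(c(g = "S"), c(g = "P"), c(g = "P"))$flow,
                 "SPP")
    expect_equal(assignFlows(c(g = "N"), c(g = "N"), c(g = "N"))$flow,
                 "NNN")
    expect_equal(length(allFlows()), 32L)
    expect_error(assignFlows("S", "S", "P"))   # S invalid at 52 hpf
})

test_that("flow queries expand with * and skin wildcards", {
    expect_setequal(expandFlowQuery("*BB"), c("NBB", "SBB"))
    expect_equal(length(expandFlowQuery("SSS")), 9L)
    expect_equal(length(expandFlowQuery("**S")), 24L)
    expect_equal(length(expandFlowQuery("***")), 32L)
    expect_setequal(expandFlowQuery("SPP"), "SPP")
    expect_error(expandFlowQuery("Q**"), "position 1")
    expect_error(expandFlowQuery("*X*"), "position 2")
    expect_error(expandFlowQuery("NNNN"), "3 characters")
})

test_that("Monte Carlo oracle classification matches the analytic rules", {
    set.seed(88)
    n <- 80
    means <- flatMeans(n); ses <- means * 0
    means[] <- 6 + rnorm(length(means), 0, 1.2)
    ses[] <- runif(length(ses), 0.05, 0.5)
    mdl <- toyModel(means, ses)
    th <- flowThresholds(mc_draws = 2e4, seed = 5)
    ana <- classifyLater(mdl, "52hpf", th)
    mc <- mcOracleClassify(mdl, "52hpf", th)
    # disagreement allowed only when a decision probability sits within
    # 3 MC standard errors of the epsilon cutoff (or the 0.5 P/B line)
    mcse <- 3 * sqrt(0.02 * 0.98 / th$mc_draws)
    for (i in which(ana != mc)) {
        pNA <- probNeitherAbove(means[i, "periderm.52hpf"],
                                ses[i, "periderm.52hpf"],
                                means[i, "basal.52hpf"],
                                ses[i, "basal.52hpf"],
                                means[i, "nonskin2.52hpf"],
                                ses[i, "nonskin2.52hpf"], th$theta)
        pND <- probNotDifferent(means[i, "periderm.52hpf"],
                                ses[i, "periderm.52hpf"],
                                means[i, "basal.52hpf"],
                                ses[i, "basal.52hpf"], th$theta)
        pPB <- probExceeds(means[i, "periderm.52hpf"],
                           ses[i, "periderm.52hpf"],
                           means[i, "basal.52hpf"],
                           ses[i, "basal.52hpf"], theta = 0)
        near <- abs(pNA - th$epsilon) < mcse ||
            abs(pND - th$epsilon) < mcse ||
            abs(pPB - 0.5) < 3 * sqrt(0.25 / th$mc_draws)
        expect_true(near)
    }
    # the oracle is deterministic under a fixed seed
    expect_identical(mc, mcOracleClassify(mdl, "52hpf", th))
})

test_that("epsilon = 0.49 forces N in both implementations together", {
    set.seed(12)
    means <- flatMeans(30); ses <- means * 0 + 0.3
    means[] <- means + rnorm(length(means), 0, 0.8)
    mdl <- toyModel(means, ses)
    th <- flowThresholds(epsilon = 0.49, mc_draws = 5e4, seed = 2)
    ana <- classifyLater(mdl, "52hpf", th)
    mc <- mcOracleClassify(mdl, "52hpf", th)
    expect_gt(mean(ana == mc), 0.9)
})
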