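lowCost <- parameterCombination("low_cost", jitterScale = 0)

test_that("fixed points satisfy the residual contract and include vertices", {
    set.seed(1)
    fp <- findFixedPoints(Community("[PD,SP,DS]"), lowCost,
                          costs = identicalCosts(lowCost, 2))
    expect_true(all(fp$residual < 1e-10))
    # the three fixation states are present
    for (v in 1:3) {
        d <- apply(abs(t(as.matrix(fp[, 1:3])) - diag(3)[v, ]), 2, max)
        expect_true(any(d < 1e-6))
    }
    expect_true(all(fp$spectralRadius >= 0))
    expect_true(all(fp$robustness[!(fp$stable & fp$interior)] == 0))
})

test_that("the circulant two-motif community coexists at low cost while
          the one-antibiotic motif does not", {
    set.seed(2)
    fp <- findFixedPoints(Community("[PD,SP,DS]"), lowCost,
                          costs = identicalCosts(lowCost, 2))
    expect_gte(sum(fp$stable & fp$interior), 1L)
    set.seed(2)
    fp1 <- findFixedPoints(Community("[P,S,D]"), lowCost,
                           costs = identicalCosts(lowCost, 1))
    expect_equal(sum(fp1$stable & fp1$interior), 0L)
})

test_that("the barycentre appears among fixed points of the circulant
          three-motif community", {
    set.seed(3)
    fp <- findFixedPoints(Community("[PDS,SPD,DSP]"), lowCost,
                          costs = identicalCosts(lowCost, 3))
    d <- apply(abs(t(as.matrix(fp[, 1:3])) - 1/3), 2, max)
    expect_true(any(d < 1e-8))
    expect_true(fp$stable[which.min(d)])
})

test_that("spectral radius classifies vertices correctly", {
    # sensitive fixation in [P,S,D] is attracting
    rho <- jacobianSpectralRadius(Community("[P,S,D]"), lowCost,
                                  c(0, 1, 0),
                                  costs = identicalCosts(lowCost, 1))
    expect_lt(rho, 1)
    # residual contract: a non-fixed point is rejected
    expect_error(jacobianSpectralRadius(Community("[PD,SP,DS]"), lowCost,
                                        c(0.3, 0.3, 0.4),
                                        costs = identicalCosts(lowCost, 2)),
                 "residual")
})

test_that("identical strains give a neutral (radius ~ 1) direction", {
    # duplicate phenotype rows make the map the identity on their ratio
    p <- modelParams(jitterScale = 0)
    comm <- Community("[P,P]")
    costs <- identicalCosts(p, 1)
    rho <- jacobianSpectralRadius(comm, p, c(0.4, 0.6), costs = costs)
    expect_equal(rho, 1, tolerance = 1e-6)
    set.seed(4)
    fp <- findFixedPoints(comm, p, costs = costs)
    # neutral points are never reported as stable
    expect_true(all(!fp$stable | fp$spectralRadius < 1 - 1e-9))
})

test_that("stability classification agrees with trajectory behaviour", {
    set.seed(5)
    checked <- 0L
    while (checked < 8L) {
        comm <- randomCommunity(3, 2)
        costs <- identicalCosts(lowCost, 2)
        r <- tryCatch(growthRates(comm, costs, lowCost@g),
                      error = function(e) NULL)
        if (is.null(r)) next
        fp <- findFixedPoints(comm, lowCost, costs = costs, nInit = 40)
        sel <- which(fp$stable & fp$interior)
        checked <- checked + 1L
        for (i in sel) {
            Xs <- as.numeric(fp[i, 1:3])
            pert <- Xs + runif(3, -1, 1) * 1e-3
            pert <- pmax(pert, 1e-9); pert <- pert / sum(pert)
            tr <- simulateTrajectory(comm, pert, lowCost, costs = costs,
                                     maxSteps = 1e4, record = FALSE)
            expect_lt(max(abs(tr$terminal - Xs)), 1e-2)
        }
    }
})

test_that("fixed-point search is reproducible under a seed", {
    p <- parameterCombination("low_cost")
    set.seed(77)
    costs <- realizedCosts(p, 2)
    a <- findFixedPoints(Community("[PD,SP,DS]"), p, costs = costs)
    set.seed(77)
    costs2 <- realizedCosts(p, 2)
    b <- findFixedPoints(Community("[PD,SP,DS]"), p, costs = costs2)
    expect_identical(a, b)
})

test_that("basin fractions are fractions and vanish without coexistence", {
    set.seed(6)
    expect_equal(basinFraction(Community("[P,S,D]"), lowCost,
                               costs = identicalCosts(lowCost, 1)), 0)
    set.seed(6)
    bf <- basinFraction(Community("[PD,SP,DS]"), lowCost,
                        costs = identicalCosts(lowCost, 2))
    expect_gte(bf, 0); expect_lte(bf, 1)
    expect_gt(bf, 0.5)   # most random starts reach coexistence
    # the near-circulant community has no coexistence at low cost at all
    set.seed(6)
    expect_equal(basinFraction(Community("[PD,SP,RS]"), lowCost,
                               costs = identicalCosts(lowCost, 2)), 0)
})

test_that("robustness of the circulant three-motif community is constant
          across cost ratios", {
    comm <- Community("[PDS,SPD,DSP]")
    vals <- sweepCostGrid(comm, base = "low_cost",
                          cpRatios = c(1.5, 2.5, 3.5),
                          cdRatios = c(1.2, 2.0),
                          metric = "robustness", nInit = 20, seed = 8)
    expect_true(all(vals > 0))
    expect_lt(max(vals) - min(vals), 1e-6)
})
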