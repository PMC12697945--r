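lowCost <- parameterCombination("low_cost", jitterScale = 0)

test_that("realized costs respect the jitter contract", {
    p <- modelParams(cr = 0.16, jitterScale = 0)
    costs <- realizedCosts(p, 3)
    expect_equal(costs$crJ, rep(0.16, 3))
    expect_equal(costs$cdJ, rep(0.224, 3))
    expect_equal(costs$cpJ, rep(0.4, 3))

    pj <- modelParams(cr = 0.16, jitterScale = 5e-4)
    set.seed(1)
    costs <- realizedCosts(pj, 50)
    expect_true(all(abs(costs$crJ - 0.16) <= 5e-4))
    expect_true(all(costs$crJ >= 0.1595 & costs$crJ <= 0.1605))
    set.seed(99)
    a <- realizedCosts(pj, 4)
    set.seed(99)
    expect_identical(realizedCosts(pj, 4), a)
})

test_that("growth rates follow additive phenotype costs", {
    costs <- realizedCosts(lowCost, 2)
    expect_equal(growthRates(Community("[PD,SP,DS]"), costs, 1),
                 c(0.376, 0.600, 0.776))
    costs1 <- realizedCosts(lowCost, 1)
    expect_equal(growthRates(Community("[P,S,R]"), costs1, 1),
                 c(0.6, 1.0, 0.84))
    expect_equal(growthRates(Community("[SS,SS,SS]"), costs, 1), c(1, 1, 1))
    # a strain whose costs exceed its growth rate is a configuration error
    bigM <- realizedCosts(lowCost, 3)
    expect_error(growthRates(Community("[PPP,SSS,DDD]"), bigM, 1),
                 "non-viable")
})

test_that("kill probabilities match direct evaluation of the zone model", {
    p <- modelParams(jitterScale = 0)   # KP = 40, KD = 10
    X <- rep(1/3, 3)
    kp <- killProbabilities(Community("[P,S,D]"), X, p)
    expect_equal(kp[1], 0)
    expect_equal(kp[3], 0)
    expect_equal(kp[2], exp(-10/3) * (1 - exp(-40/3)), tolerance = 1e-12)
    # no producers anywhere: no killing
    expect_equal(killProbabilities(Community("[S,D,R]"), X, p), rep(0, 3))
    # strains without any sensitivity are never killed
    kp2 <- killProbabilities(Community("[PD,DP,SS]"), c(0.2, 0.3, 0.5), p)
    expect_equal(kp2[1:2], c(0, 0))
    expect_gt(kp2[3], 0)
})

test_that("product form equals the inclusion-exclusion expansion", {
    p <- modelParams(jitterScale = 0)
    set.seed(21)
    for (i in 1:25) {
        N <- sample(2:4, 1); M <- sample(1:4, 1)
        comm <- randomCommunity(N, M)
        X <- as.vector(rdirichletStarts(1, N))
        kp <- killProbabilities(comm, X, p)
        pij <- oraclePerAntibioticKill(phenotypeMatrix(comm), X,
                                       p@KP, p@KD)
        expected <- vapply(seq_len(N), function(i)
            oracleInclusionExclusion(pij[i, ]), numeric(1))
        expect_true(all(abs(kp - expected) < 1e-12))
    }
})

test_that("the replicator step renormalizes and preserves extinctions", {
    expect_equal(replicatorStep(c(0.5, 0.5), c(1, 3)), c(0.25, 0.75))
    expect_equal(replicatorStep(c(0.2, 0.3, 0.5), c(2, 2, 2)),
                 c(0.2, 0.3, 0.5))
    expect_equal(replicatorStep(c(1, 0), c(0.3, 5)), c(1, 0))
    expect_error(replicatorStep(c(0.5, 0.5), c(0, 0)), "extinction")
})

test_that("trajectories stay on the simplex", {
    p <- modelParams(jitterScale = 0)
    set.seed(13)
    for (i in 1:5) {
        comm <- randomCommunity(3, 2)
        costs <- identicalCosts(p, 2)
        r <- tryCatch(growthRates(comm, costs, p@g), error = function(e) NULL)
        if (is.null(r)) next
        X0 <- as.vector(rdirichletStarts(1, 3))
        tr <- simulateTrajectory(comm, X0, p, costs = costs, maxSteps = 500)
        expect_true(all(abs(rowSums(tr$states) - 1) < 1e-12))
        expect_true(all(tr$states >= 0))
    }
})

test_that("dynamics are equivariant under strain and antibiotic relabelling", {
    p <- modelParams(jitterScale = 0)
    set.seed(31)
    for (i in 1:5) {
        comm <- Community("[PDS,SPD,RSP]")
        costs <- list(crJ = c(0.16, 0.161, 0.159),
                      cdJ = c(0.224, 0.223, 0.225),
                      cpJ = c(0.400, 0.401, 0.399))
        rp <- sample(3); cp <- sample(3)
        permComm <- Community(phenotypeMatrix(comm)[rp, cp])
        permCosts <- list(crJ = costs$crJ[cp], cdJ = costs$cdJ[cp],
                          cpJ = costs$cpJ[cp])
        X0 <- as.vector(rdirichletStarts(1, 3))
        t1 <- simulateTrajectory(comm, X0, p, costs = costs,
                                 maxSteps = 200, record = FALSE)
        t2 <- simulateTrajectory(permComm, X0[rp], p, costs = permCosts,
                                 maxSteps = 200, record = FALSE)
        expect_equal(t2$terminal, t1$terminal[rp], tolerance = 1e-12)
    }
})

test_that("the barycentre is a machine-precision fixed point of the
          circulant three-motif community", {
    p <- modelParams(jitterScale = 0)
    comm <- Community("[PDS,SPD,DSP]")
    costs <- identicalCosts(p, 3)
    X <- rep(1/3, 3)
    f <- growthRates(comm, costs, p@g) * (1 - killProbabilities(comm, X, p))
    expect_equal(replicatorStep(X, f), X, tolerance = 1e-15)
})

test_that("well-mixed [P,S,D] always ends in sensitive fixation", {
    p <- modelParams(jitterScale = 0)
    costs <- identicalCosts(p, 1)
    comm <- Community("[P,S,D]")
    set.seed(17)
    for (i in 1:5) {
        X0 <- as.vector(rdirichletStarts(1, 3))
        tr <- simulateTrajectory(comm, X0, p, costs = costs, record = FALSE)
        expect_true(tr$converged)
        expect_equal(tr$terminal[2], 1, tolerance = 1e-8)
    }
    # vertices are fixed
    tr <- simulateTrajectory(comm, c(1, 0, 0), p, costs = costs,
                             maxSteps = 50, record = FALSE)
    expect_equal(tr$terminal, c(1, 0, 0))
})

test_that("[P,S,R] fixes one strain, which strain depends on parameters", {
    set.seed(23)
    comm <- Community("[P,S,R]")
    # low resistance cost: the resistant strain can win; cheap sensitivity
    # always competes. Either way a single strain fixes.
    for (cr in c(0.02, 0.16)) {
        p <- suppressWarnings(modelParams(cr = cr, cd = 0.224, cp = 0.4,
                                          jitterScale = 0))
        costs <- identicalCosts(p, 1)
        tr <- simulateTrajectory(comm, c(0.4, 0.3, 0.3), p, costs = costs,
                                 record = FALSE)
        expect_equal(sort(tr$terminal, decreasing = TRUE)[1], 1,
                     tolerance = 1e-6)
    }
})
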