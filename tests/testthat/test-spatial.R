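psd <- Community("[P,S,D]")

test_that("lattice initialization follows the occupancy model", {
    sp <- spatialParams(gridSize = 40, pInit = 0)
    set.seed(1)
    st <- initLattice(sp, psd)
    expect_true(all(st@occupancy == 0L))

    sp <- spatialParams(gridSize = 40, pInit = 0.5)
    set.seed(2)
    st <- initLattice(sp, psd)
    n <- 40 * 40
    frac <- mean(st@occupancy > 0)
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
    counts <- tabulate(st@occupancy, 3)
    expect_lt(max(counts) / sum(counts), 1/3 + 3 * sqrt(2/9 / sum(counts)))
    expect_true(all(vapply(st@antibioticFields, function(f) all(f == 0),
                           TRUE)))
})

test_that("chemical fields are convolutions of the source maps", {
    sp <- spatialParams(gridSize = 30, KP = 4, KD = 2)
    st <- new("LatticeState", occupancy = matrix(0L, 30, 30),
              antibioticFields = list(matrix(0, 30, 30)),
              enzymeFields = list(matrix(0, 30, 30)),
              generation = 0L, birthGeneration = matrix(0L, 30, 30))
    # no producers anywhere: zero field
    st@occupancy[5, 5] <- 2L   # a sensitive individual only
    f <- computeFields(st, psd, sp)
    expect_true(all(f@antibioticFields[[1]] == 0))
    expect_true(all(f@enzymeFields[[1]] == 0))

    # single producer: field sums to up x kernel mass, peak at the source
    st@occupancy[,] <- 0L
    st@occupancy[10, 12] <- 1L
    f <- computeFields(st, psd, sp)
    kern <- AMICoex:::.hexKernel(30, sp@KP)
    expect_equal(sum(f@antibioticFields[[1]]), sp@up * sum(kern),
                 tolerance = 1e-9)
    expect_equal(which.max(f@antibioticFields[[1]]),
                 which(st@occupancy == 1L))
    expect_equal(max(f@antibioticFields[[1]]), sp@up, tolerance = 1e-9)

    # linearity: doubling the producers doubles the field
    st2 <- st; st2@occupancy[20, 3] <- 1L
    f2 <- computeFields(st2, psd, sp)
    single2 <- computeFields({
        s <- st; s@occupancy[,] <- 0L; s@occupancy[20, 3] <- 1L; s
    }, psd, sp)
    expect_equal(f2@antibioticFields[[1]],
                 f@antibioticFields[[1]] + single2@antibioticFields[[1]],
                 tolerance = 1e-9)
})

test_that("hexagonal sites have six periodic neighbours", {
    # the kernel at K -> 0+ touches only the site itself; at small K the six
    # nearest neighbours carry equal weight (distance 1 in hex embedding)
    kern <- AMICoex:::.hexKernel(12, 0.2)
    w <- sort(kern[kern > 0], decreasing = TRUE)
    expect_equal(w[1], 1)
    expect_equal(length(w), 7L)               # self + 6 equidistant
    expect_equal(w[2:7], rep(exp(-1 / 0.4), 6), tolerance = 1e-12)
})

test_that("demography follows the death/birth rules", {
    # certain death empties the lattice in one generation
    sp <- spatialParams(gridSize = 20, d = 1)
    set.seed(3)
    st <- initLattice(sp, psd)
    st <- computeFields(st, psd, sp)
    st <- stepGeneration(st, psd, sp)
    expect_true(all(st@occupancy == 0L))
    expect_equal(st@generation, 1L)

    # at zero antibiotic exposure a sensitive individual dies at rate d
    sp2 <- spatialParams(gridSize = 20, d = 0.3)
    st2 <- new("LatticeState", occupancy = matrix(0L, 20, 20),
               antibioticFields = list(matrix(0, 20, 20)),
               enzymeFields = list(matrix(0, 20, 20)),
               generation = 0L, birthGeneration = matrix(0L, 20, 20))
    st2@occupancy[4, 4] <- 2L
    dp <- AMICoex:::.deathProbabilities(st2, psd, sp2)
    expect_equal(dp[4, 4], 0.3)
    expect_equal(sum(dp), 0.3)   # empty sites have death probability 0
})

test_that("occupancy changes only through births into empty neighbours and
          deaths", {
    sp <- spatialParams(gridSize = 15, KP = 1, KD = 1)
    set.seed(4)
    st <- initLattice(sp, psd)
    nbrOffsets <- cbind(dq = c(1, -1, 0, 0, 1, -1),
                        dr = c(0, 0, 1, -1, -1, 1))
    L <- 15
    for (gen in 1:30) {
        prev <- st@occupancy
        st <- computeFields(st, psd, sp)
        st <- stepGeneration(st, psd, sp)
        cur <- st@occupancy
        changed <- which(prev != cur, arr.ind = TRUE)
        for (k in seq_len(nrow(changed))) {
            q <- changed[k, 1]; r <- changed[k, 2]
            if (cur[q, r] == 0L) next     # death: always allowed
            # birth (possibly into a site whose occupant died earlier in
            # the same generation): some neighbour must have carried the
            # parent strain at the start of the generation
            nbrStrains <- vapply(seq_len(6), function(o) {
                qq <- (q - 1 + nbrOffsets[o, 1]) %% L + 1
                rr <- (r - 1 + nbrOffsets[o, 2]) %% L + 1
                prev[qq, rr]
            }, integer(1))
            expect_true(cur[q, r] %in% nbrStrains)
        }
    }
})

test_that("without antibiotic reach the cheapest strain wins", {
    # KP = 0: the antibiotic touches only the producer's own site, so the
    # dynamics reduce to cost-ordered contact competition and the sensitive
    # strain (no cost) takes over, as in the well-mixed [P,S,D] outcome
    sp <- spatialParams(gridSize = 30, KP = 0, KD = 0, generations = 800)
    set.seed(5)
    tr <- runSpatial(psd, sp)
    last <- unlist(tr[nrow(tr), c("count_1", "count_2", "count_3")])
    expect_gt(last[2] / sum(last), 0.95)
})

test_that("spatial runs are bit-reproducible under a seed", {
    sp <- spatialParams(gridSize = 15, KP = 2, KD = 1)
    set.seed(11)
    a <- runSpatial(psd, sp, generations = 40)
    set.seed(11)
    b <- runSpatial(psd, sp, generations = 40)
    expect_identical(a, b)
    expect_identical(attr(a, "state")@occupancy, attr(b, "state")@occupancy)
})

test_that("neutral labels stay balanced in expectation", {
    # no producers and zero costs: strain labels are exchangeable, so mean
    # abundances across replicates stay approximately equal
    comm <- Community("[S,S,S]")
    sp <- spatialParams(gridSize = 25, cr = 0, cd = 0, cp = 0, g = 0.6)
    set.seed(6)
    tot <- c(0, 0, 0)
    for (rep in 1:6) {
        tr <- runSpatial(comm, sp, generations = 60)
        tot <- tot + unlist(tr[nrow(tr), c("count_1", "count_2", "count_3")])
    }
    expect_lt(max(tot) / sum(tot), 1/3 + 0.08)
})
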