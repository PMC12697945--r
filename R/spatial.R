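#' Construct spatial-model parameters
#'
#' Defaults are the demographic parameters of the lattice experiments:
#' birth scale 0.7, baseline death 0.3, costs (cr, cd, cp) =
#' (0.05, 0.105, 0.15), secretion amounts up = ud = 10, grid 200 x 200,
#' and half-occupied initial lattices.
#'
#' @param g birth probability scale.
#' @param d baseline death probability.
#' @param cr,cd,cp phenotype costs subtracted from g.
#' @param KP,KD antibiotic and enzyme diffusivities (lattice-unit^2 per
#'   generation).
#' @param up,ud secretion amount per producer / degrader individual.
#' @param gridSize lattice side length.
#' @param pInit initial occupancy probability.
#' @param generations,replicates default experiment sizes.
#' @return a \code{\linkS4class{SpatialParams}}.
#' @export
spatialParams <- function(g = 0.7, d = 0.3, cr = 0.05, cd = 0.105,
                          cp = 0.15, KP = 10, KD = 10, up = 10, ud = 10,
                          gridSize = 200L, pInit = 0.5,
                          generations = 6000L, replicates = 15L) {
    new("SpatialParams", g = g, d = d, cr = cr, cd = cd, cp = cp,
        KP = KP, KD = KD, up = up, ud = ud,
        gridSize = as.integer(gridSize), pInit = pInit,
        generations = as.integer(generations),
        replicates = as.integer(replicates))
}

# Periodic isotropic secretion kernel on the axial hexagonal torus:
# unnormalized Gaussian exp(-dist^2 / (2K)) truncated at 3*sqrt(K), with
# distances taken in the hexagonal embedding under minimum image. The
# kernel is unnormalized on purpose: a larger K both widens the reach and
# raises the total exposure, so K acts as diffusivity and susceptibility at
# once. K = 0 degenerates to a point source at distance 0 only.
.hexKernel <- function(L, K) {
    idx <- seq_len(L) - 1L
    shift <- c(0, L, -L)
    d2 <- matrix(Inf, L, L)
    for (a in shift) for (b in shift) {
        dq <- outer(idx + a, rep(1, L))
        dr <- outer(rep(1, L), idx + b)
        cand <- (dq + dr / 2)^2 + 0.75 * dr^2
        d2 <- pmin(d2, cand)
    }
    cutoff2 <- if (K > 0) (3 * sqrt(K))^2 else 0
    kern <- matrix(0, L, L)
    inside <- d2 <= cutoff2
    if (K > 0) kern[inside] <- exp(-d2[inside] / (2 * K))
    kern[1L, 1L] <- 1      # self site (distance 0), any K
    kern
}

.periodicConvolve <- function(src, kernFFT) {
    n <- length(src)
    out <- Re(stats::fft(stats::fft(src) * kernFFT, inverse = TRUE)) / n
    pmax(out, 0)
}

#' Initialize a lattice
#'
#' Each site is independently occupied with probability \code{pInit}; the
#' occupant's strain is uniform on 1..N. Chemical fields start at zero and
#' are filled in by \code{\link{computeFields}}. Draws from the current RNG
#' stream.
#'
#' @param sp a \code{\linkS4class{SpatialParams}}.
#' @param community the \code{\linkS4class{Community}} being simulated.
#' @return a \code{\linkS4class{LatticeState}}.
#' @export
initLattice <- function(sp, community) {
    L <- sp@gridSize
    N <- nStrains(community)
    M <- nAntibiotics(community)
    occupied <- stats::runif(L * L) < sp@pInit
    occ <- matrix(0L, L, L)
    occ[occupied] <- sample.int(N, sum(occupied), replace = TRUE)
    zero <- matrix(0, L, L)
    new("LatticeState", occupancy = occ,
        antibioticFields = rep(list(zero), M),
        enzymeFields = rep(list(zero), M),
        generation = 0L,
        birthGeneration = matrix(0L, L, L))
}

#' Recompute the quasi-static chemical fields
#'
#' Production and degradation are fast relative to cell division, so each
#' generation the antibiotic and enzyme concentration fields are recomputed
#' from scratch from the current occupancy: per antibiotic, the field is
#' the source map (secretion amount at each producer / degrader site)
#' convolved with the periodic hexagonal secretion kernel of spread KP /
#' KD. No concentration carries over between generations.
#'
#' @param state a \code{\linkS4class{LatticeState}}.
#' @param community the \code{\linkS4class{Community}}.
#' @param sp a \code{\linkS4class{SpatialParams}}.
#' @param kernels optional precomputed kernel FFT list (internal cache).
#' @return the state with updated fields.
#' @export
computeFields <- function(state, community, sp, kernels = NULL) {
    L <- sp@gridSize
    M <- nAntibiotics(community)
    ind <- indicatorMatrices(community)
    if (is.null(kernels))
        kernels <- list(P = stats::fft(.hexKernel(L, sp@KP)),
                        D = stats::fft(.hexKernel(L, sp@KD)))
    occ <- state@occupancy
    for (j in seq_len(M)) {
        producers <- which(ind$P[, j] == 1)
        degraders <- which(ind$D[, j] == 1)
        srcP <- matrix(as.numeric(occ %in% producers) * sp@up, L, L)
        srcD <- matrix(as.numeric(occ %in% degraders) * sp@ud, L, L)
        state@antibioticFields[[j]] <-
            if (any(srcP > 0)) .periodicConvolve(srcP, kernels$P)
            else matrix(0, L, L)
        state@enzymeFields[[j]] <-
            if (any(srcD > 0)) .periodicConvolve(srcD, kernels$D)
            else matrix(0, L, L)
    }
    state
}

# Per-site death probabilities for the current occupants: the local
# effective antibiotic concentration is attenuated exponentially by the
# local enzyme field, the per-antibiotic kill probability is
# 1 - exp(-a_eff) for sensitive occupants, antibiotic risks combine
# independently, and the baseline death risk d composes as
# 1 - (1-d)(1-q).
.deathProbabilities <- function(state, community, sp) {
    occ <- state@occupancy
    ind <- indicatorMatrices(community)
    M <- nAntibiotics(community)
    L <- nrow(occ)
    logSurvive <- matrix(0, L, L)
    for (j in seq_len(M)) {
        aeff <- state@antibioticFields[[j]] * exp(-state@enzymeFields[[j]])
        qj <- 1 - exp(-aeff)
        sens <- occ > 0 & ind$S[, j][pmax(occ, 1L)] == 1
        logSurvive[sens] <- logSurvive[sens] + log1p(-qj[sens])
    }
    q <- 1 - exp(logSurvive)
    dp <- 1 - (1 - sp@d) * (1 - q)
    dp[occ == 0L] <- 0
    dp
}

.birthProbabilities <- function(community, sp) {
    ind <- indicatorMatrices(community)
    r <- sp@g - rowSums(ind$P) * sp@cp - rowSums(ind$D) * sp@cd -
        rowSums(ind$R) * sp@cr
    if (any(r < 0) || any(r > 1))
        stop("birth probabilities g - costs must lie in [0, 1]; got ",
             paste(signif(r, 4), collapse = ", "))
    r
}

#' Advance the lattice by one generation
#'
#' Sites are visited in a fresh random order. Each occupant present at the
#' start of the generation dies with probability 1 - (1-d)(1-q), where q is
#' its antibiotic kill probability from the local effective concentrations;
#' a survivor gives birth with probability g minus its phenotype costs into
#' a uniformly chosen empty neighbour (of its 6), if any. Newborns are not
#' visited in the generation of their birth. Fields must be freshly
#' computed for the current occupancy (see \code{\link{computeFields}}).
#'
#' @param state a \code{\linkS4class{LatticeState}} with current fields.
#' @param community the \code{\linkS4class{Community}}.
#' @param sp a \code{\linkS4class{SpatialParams}}.
#' @return the updated \code{\linkS4class{LatticeState}}.
#' @export
stepGeneration <- function(state, community, sp) {
    L <- sp@gridSize
    dp <- .deathProbabilities(state, community, sp)
    bp <- .birthProbabilities(community, sp)
    order <- sample.int(L * L)
    state@occupancy <- step_generation_cpp(state@occupancy, order,
                                           as.vector(dp), bp)
    state@generation <- state@generation + 1L
    state
}

#' Run a spatial simulation and record strain abundances
#'
#' @param community the \code{\linkS4class{Community}}.
#' @param sp a \code{\linkS4class{SpatialParams}}.
#' @param generations number of generations (defaults to
#'   \code{sp@generations}).
#' @param state optional pre-initialized lattice (otherwise
#'   \code{\link{initLattice}} is called).
#' @return data.frame with columns \code{generation}, \code{count_1..N} and
#'   \code{occupied} (fraction of sites); the final
#'   \code{\linkS4class{LatticeState}} is attached as attribute
#'   \code{"state"}.
#' @export
runSpatial <- function(community, sp, generations = sp@generations,
                       state = NULL) {
    L <- sp@gridSize
    N <- nStrains(community)
    .birthProbabilities(community, sp)   # validate up front
    kernels <- list(P = stats::fft(.hexKernel(L, sp@KP)),
                    D = stats::fft(.hexKernel(L, sp@KD)))
    if (is.null(state)) state <- initLattice(sp, community)
    counts <- matrix(0L, generations + 1L, N)
    occFrac <- numeric(generations + 1L)
    tab <- tabulate(state@occupancy, nbins = N)
    counts[1L, ] <- tab
    occFrac[1L] <- sum(tab) / (L * L)
    for (gen in seq_len(generations)) {
        state <- computeFields(state, community, sp, kernels)
        state <- stepGeneration(state, community, sp)
        tab <- tabulate(state@occupancy, nbins = N)
        counts[gen + 1L, ] <- tab
        occFrac[gen + 1L] <- sum(tab) / (L * L)
        if (occFrac[gen + 1L] == 0) {
            counts <- counts[seq_len(gen + 1L), , drop = FALSE]
            occFrac <- occFrac[seq_len(gen + 1L)]
            break
        }
    }
    out <- data.frame(generation = seq_len(nrow(counts)) - 1L, counts,
                      occupied = occFrac)
    names(out) <- c("generation", paste0("count_", seq_len(N)), "occupied")
    attr(out, "state") <- state
    out
}

#' Phase diagram over antibiotic and enzyme diffusivities
#'
#' For each (KP, KD) grid point, runs independent replicate simulations
#' from different initial configurations (the occupied fraction is held
#' constant across replicates) and reports per-strain abundances as
#' fractions of all lattice sites, averaged over the final
#' \code{lastWindow} generations.
#'
#' @param community the \code{\linkS4class{Community}} (any community; the
#'   canonical experiment uses \code{[P,S,D]}).
#' @param sp a \code{\linkS4class{SpatialParams}} supplying everything but
#'   the diffusivities.
#' @param KPgrid,KDgrid diffusivity grids.
#' @param replicates,generations experiment size (default 15 and 6000).
#' @param lastWindow number of final generations averaged.
#' @param seed master seed; each (KP, KD, replicate) cell gets a derived
#'   substream so cells are independent of execution order.
#' @return data.frame with one row per (KP, KD, replicate) and columns
#'   \code{mean_1..N} (site fractions) and \code{occupied}.
#' @export
runPhaseDiagram <- function(community, sp, KPgrid, KDgrid,
                            replicates = sp@replicates,
                            generations = sp@generations,
                            lastWindow = 500L, seed = 1L) {
    N <- nStrains(community)
    rows <- list()
    for (KP in KPgrid) for (KD in KDgrid) for (rep in seq_len(replicates)) {
        spc <- sp
        spc@KP <- KP
        spc@KD <- KD
        set.seed(.substreamSeed(seed, sprintf("phase|%g|%g|%d",
                                              KP, KD, rep)))
        tr <- runSpatial(community, spc, generations = generations)
        w <- max(1L, nrow(tr) - lastWindow + 1L)
        win <- tr[w:nrow(tr), , drop = FALSE]
        meanCounts <- colMeans(win[, paste0("count_", seq_len(N)),
                                   drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(
            KP = KP, KD = KD, replicate = rep,
            t(meanCounts / spc@gridSize^2),
            occupied = mean(win$occupied))
    }
    out <- do.call(rbind, rows)
    names(out) <- c("KP", "KD", "replicate",
                    paste0("mean_", seq_len(N)), "occupied")
    out
}
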