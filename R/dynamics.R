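#' Construct model parameters for the mixed-inhibition zone model
#'
#' @param g base growth rate per generation.
#' @param cr,cd,cp costs of intrinsic resistance, degradation, production.
#'   The expected ordering is \code{cr <= cd <= cp} (production is the most
#'   expensive phenotype, then degradation, then resistance); a violation is
#'   permitted, since parameter sweeps cross the ratios, but is flagged with
#'   a warning.
#' @param KP,KD antibiotic and degrader strengths (effective killing /
#'   degradation areas entering the exponential kill terms).
#' @param jitterScale half-width of the per-antibiotic uniform perturbation
#'   added to the realized cost of resistance; the default 5e-4 removes
#'   edge-case degeneracies that exist only at exactly identical costs.
#' @return a \code{\linkS4class{ModelParams}}.
#' @export
modelParams <- function(g = 1, cr = 0.16, cd = 1.4 * cr, cp = 2.5 * cr,
                        KP = 40, KD = 10, jitterScale = 0.0005) {
    if (!(cr <= cd && cd <= cp))
        warning("unusual cost ordering: expected cr <= cd <= cp, got cr=",
                cr, ", cd=", cd, ", cp=", cp)
    new("ModelParams", g = g, cr = cr, cd = cd, cp = cp, KP = KP, KD = KD,
        jitterScale = jitterScale)
}

#' The two reference parameter combinations
#'
#' The exhaustive topology surveys are run at two named cost structures
#' sharing g = 1, cr = 0.16, KP = 40, KD = 10: \code{"low_cost"} has
#' cd = 1.4 cr and cp = 2.5 cr; \code{"high_cost"} has cd = 2.2083 cr and
#' cp = 2.7624 cr.
#'
#' @param label \code{"low_cost"} or \code{"high_cost"}.
#' @param jitterScale see \code{\link{modelParams}}; surveys keep the
#'   default jitter on, community-comparison sweeps set it to 0.
#' @return a \code{\linkS4class{ModelParams}}.
#' @export
parameterCombination <- function(label = c("low_cost", "high_cost"),
                                 jitterScale = 0.0005) {
    label <- match.arg(label)
    cr <- 0.16
    if (label == "low_cost")
        modelParams(g = 1, cr = cr, cd = 1.4 * cr, cp = 2.5 * cr,
                    KP = 40, KD = 10, jitterScale = jitterScale)
    else
        modelParams(g = 1, cr = cr, cd = 2.2083 * cr, cp = 2.7624 * cr,
                    KP = 40, KD = 10, jitterScale = jitterScale)
}

#' Draw realized per-antibiotic costs
#'
#' Every phenotype cost is similar but not exactly identical across the
#' antibiotics: the realized cost of each phenotype for antibiotic j is the
#' base cost plus \code{jitterScale * U(-1, 1)}, drawn independently per
#' phenotype and per antibiotic from the current RNG stream (use
#' \code{set.seed} for reproducibility), so the realized cost of resistance
#' is \code{cr + jitterScale * U(-1, 1)} and degradation and production get
#' their own perturbations of the same scale. Independent draws are what
#' break every cost degeneracy between strains (e.g. the mirror strains
#' (P,D) and (D,P), whose total costs stay exactly equal under any shared
#' or ratio-scaled perturbation), which is the stated purpose of the
#' jitter; scaling a shared draw through the cost ratios would also amplify
#' it several-fold. With \code{jitterScale = 0} the base costs are
#' reproduced exactly.
#'
#' @param params a \code{\linkS4class{ModelParams}}.
#' @param M number of antibiotics.
#' @return list with numeric vectors \code{crJ}, \code{cdJ}, \code{cpJ} of
#'   length M.
#' @export
realizedCosts <- function(params, M) {
    stopifnot(M >= 1)
    js <- params@jitterScale
    list(crJ = params@cr + js * stats::runif(M, -1, 1),
         cdJ = params@cd + js * stats::runif(M, -1, 1),
         cpJ = params@cp + js * stats::runif(M, -1, 1))
}

#' Strain growth rates under additive phenotype costs
#'
#' r_i = g - sum_j cpJ_j P_ij - sum_j cdJ_j D_ij - sum_j crJ_j R_ij.
#' Sensitivity carries no cost. A strain whose costs consume its whole
#' growth rate is not viable and raises a configuration error.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @param costs realized costs from \code{\link{realizedCosts}}.
#' @param g base growth rate.
#' @return numeric vector of N growth rates, all positive.
#' @export
growthRates <- function(community, costs, g) {
    r <- .growthRatesRaw(community, costs, g)
    if (any(r <= 0))
        stop("non-viable strain(s) ",
             paste(which(r <= 0), collapse = ", "),
             ": growth rate <= 0 at these costs")
    r
}

.growthRatesRaw <- function(community, costs, g) {
    ind <- indicatorMatrices(community)
    M <- nAntibiotics(community)
    stopifnot(length(costs$crJ) == M)
    as.vector(g - ind$P %*% costs$cpJ - ind$D %*% costs$cdJ -
                  ind$R %*% costs$crJ)
}

# Precomputed evaluation context: indicator matrices, growth rates and
# strengths, used by all batched map evaluations.
.modelContext <- function(community, params, costs) {
    ind <- indicatorMatrices(community)
    r <- .growthRatesRaw(community, costs, params@g)
    list(P = ind$P, S = ind$S, D = ind$D, tS = t(ind$S), r = r,
         KP = params@KP, KD = params@KD,
         N = nStrains(community), M = nAntibiotics(community))
}

# Batched kill probabilities: X is k x N (rows are states); returns k x N.
# Per antibiotic j the kill term for a sensitive strain is
# exp(-KD sum_k Dkj Xk) * (1 - exp(-KP sum_k Pkj Xk)); terms combine across
# antibiotics as independent risks (the product form is the closed form of
# the inclusion-exclusion expansion).
.batchKill <- function(ctx, X) {
    PX <- X %*% ctx$P                       # k x M producer coverage
    DX <- X %*% ctx$D                       # k x M degrader coverage
    A <- exp(-ctx$KD * DX) * (1 - exp(-ctx$KP * PX))
    # cap just below 1 so log1p stays finite (0 * -Inf would poison the
    # masking matmul); the kill probability itself is unchanged to within
    # double precision
    A <- pmin(A, 1 - 1e-15)
    1 - exp(log1p(-A) %*% ctx$tS)           # k x N
}

# One replicator step for a batch of states (k x N); rows renormalized.
# strict = TRUE enforces the extinction contract (true dynamics, where
# X >= 0 guarantees a nonnegative total); the fixed-point solver probes
# slightly off-simplex states for finite differences, where a nonpositive
# total just marks a garbage state, floored so the iteration can move on.
.batchMap <- function(ctx, X, strict = TRUE) {
    f <- (1 - .batchKill(ctx, X)) * rep(ctx$r, each = nrow(X))
    W <- X * f
    tot <- rowSums(W)
    if (strict && any(tot <= 0))
        stop("total extinction: all fitness-weighted abundances are zero")
    W / pmax(tot, 1e-300)
}

#' Kill probabilities for a single state
#'
#' Probability that an individual of each strain dies from at least one
#' antibiotic, given current relative abundances X: per antibiotic the kill
#' probability is masked by sensitivity, attenuated exponentially by the
#' total degrader coverage, and saturates exponentially in the total
#' producer coverage; antibiotics combine as independent risks (equivalent
#' to the inclusion-exclusion expansion).
#'
#' @param community a \code{\linkS4class{Community}}.
#' @param X numeric vector of N relative abundances on the simplex.
#' @param params a \code{\linkS4class{ModelParams}}.
#' @return numeric vector of N probabilities in [0, 1].
#' @examples
#' killProbabilities(Community("[P,S,D]"), rep(1/3, 3), modelParams())
#' @export
killProbabilities <- function(community, X, params) {
    ind <- indicatorMatrices(community)
    ctx <- list(P = ind$P, S = ind$S, D = ind$D, tS = t(ind$S),
                KP = params@KP, KD = params@KD)
    as.vector(.batchKill(ctx, matrix(X, nrow = 1L)))
}

#' One step of the discrete replicator map
#'
#' X'_i = f_i X_i / sum_k f_k X_k. The output stays on the simplex and
#' extinct strains stay extinct.
#'
#' @param X state vector on the simplex.
#' @param f nonnegative fitness vector (growth rate times survival
#'   probability).
#' @return the updated state vector.
#' @export
replicatorStep <- function(X, f) {
    stopifnot(length(X) == length(f), all(f >= 0))
    w <- f * X
    tot <- sum(w)
    if (tot <= 0)
        stop("total extinction: all fitness-weighted abundances are zero")
    w / tot
}

#' Iterate the replicator dynamics to (approximate) convergence
#'
#' Repeatedly applies fitness evaluation and the replicator step until the
#' sup-norm change falls below \code{tol} or \code{maxSteps} is reached.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @param X0 initial state on the simplex.
#' @param params a \code{\linkS4class{ModelParams}}.
#' @param costs realized costs; by default drawn via
#'   \code{\link{realizedCosts}} (set \code{jitterScale = 0} in
#'   \code{params} for exactly identical costs).
#' @param maxSteps iteration cap.
#' @param tol sup-norm convergence tolerance on the step change.
#' @param interiorThreshold entries above this count as nonzero when
#'   deciding whether the terminal state is interior.
#' @param record keep the full trajectory (matrix of states) or only the
#'   terminal state.
#' @return list with \code{terminal} (state vector), \code{converged}
#'   (flag), \code{interior} (flag), \code{steps} (count) and, if recorded,
#'   \code{states} (steps+1 x N matrix including X0).
#' @export
simulateTrajectory <- function(community, X0, params, costs = NULL,
                               maxSteps = 1e5, tol = 1e-13,
                               interiorThreshold = 1e-6, record = TRUE) {
    stopifnot(abs(sum(X0) - 1) < 1e-8, all(X0 >= 0))
    if (is.null(costs))
        costs <- realizedCosts(params, nAntibiotics(community))
    ctx <- .modelContext(community, params, costs)
    X <- matrix(X0, nrow = 1L)
    states <- if (record) matrix(NA_real_, maxSteps + 1L, length(X0))
    if (record) states[1L, ] <- X0
    converged <- FALSE
    step <- 0L
    while (step < maxSteps) {
        Xn <- .batchMap(ctx, X)
        step <- step + 1L
        if (record) states[step + 1L, ] <- Xn
        if (max(abs(Xn - X)) < tol) {
            X <- Xn
            converged <- TRUE
            break
        }
        X <- Xn
    }
    terminal <- as.vector(X)
    out <- list(terminal = terminal, converged = converged,
                interior = all(terminal > interiorThreshold), steps = step)
    if (record) out$states <- states[seq_len(step + 1L), , drop = FALSE]
    out
}

#' Export a trajectory to CSV with a JSON parameter header record
#'
#' @param trajectory result of \code{\link{simulateTrajectory}} with
#'   \code{record = TRUE}.
#' @param file CSV output path (columns step, X_1..X_N); parameters and the
#'   seed are echoed to \code{<file>.json}.
#' @param params the \code{\linkS4class{ModelParams}} used.
#' @param seed the seed used, for the metadata record.
#' @return the CSV path, invisibly.
#' @export
exportTrajectory <- function(trajectory, file, params, seed = NA) {
    st <- trajectory$states
    df <- data.frame(step = seq_len(nrow(st)) - 1L, st)
    names(df) <- c("step", paste0("X_", seq_len(ncol(st))))
    utils::write.csv(df, file, row.names = FALSE)
    meta <- list(g = params@g, cr = params@cr, cd = params@cd, cp = params@cp,
                 KP = params@KP, KD = params@KD,
                 jitterScale = params@jitterScale, seed = seed,
                 converged = trajectory$converged, steps = trajectory$steps)
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
    invisible(file)
}
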