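# Fixed-point machinery. All computations use the (N-1)-dimensional simplex
# chart (the last coordinate is 1 minus the rest), so the trivial direction
# induced by normalization cannot pollute Jacobians or spectral radii.

.chartToFull <- function(y) {
    cbind(y, 1 - rowSums(y), deparse.level = 0)
}

.chartMap <- function(ctx, y) {
    X <- .chartToFull(y)
    .batchMap(ctx, X, strict = FALSE)[, -ncol(X), drop = FALSE]
}

# Batched central-difference Jacobian of the chart map: returns an
# k x d x d array J[s, i, j] = d F_i / d y_j at y[s, ].
.chartJacobian <- function(ctx, y, h = 1e-7) {
    k <- nrow(y); d <- ncol(y)
    J <- array(0, c(k, d, d))
    for (j in seq_len(d)) {
        yp <- y; yp[, j] <- yp[, j] + h
        ym <- y; ym[, j] <- ym[, j] - h
        J[, , j] <- (.chartMap(ctx, yp) - .chartMap(ctx, ym)) / (2 * h)
    }
    J
}

# Vectorized solve of (J - I) delta = -G for d <= 3 (closed forms); loops
# for larger d. Rows with a singular system get a plain map-step fallback.
.newtonStep <- function(J, G) {
    k <- nrow(G); d <- ncol(G)
    A <- J
    for (i in seq_len(d)) A[, i, i] <- A[, i, i] - 1
    delta <- matrix(NA_real_, k, d)
    if (d == 1L) {
        a <- A[, 1, 1]
        delta[, 1] <- -G[, 1] / a
        bad <- abs(a) < 1e-14
    } else if (d == 2L) {
        det <- A[, 1, 1] * A[, 2, 2] - A[, 1, 2] * A[, 2, 1]
        delta[, 1] <- -(A[, 2, 2] * G[, 1] - A[, 1, 2] * G[, 2]) / det
        delta[, 2] <- -(A[, 1, 1] * G[, 2] - A[, 2, 1] * G[, 1]) / det
        bad <- abs(det) < 1e-14
    } else if (d == 3L) {
        c11 <- A[, 2, 2] * A[, 3, 3] - A[, 2, 3] * A[, 3, 2]
        c12 <- A[, 2, 3] * A[, 3, 1] - A[, 2, 1] * A[, 3, 3]
        c13 <- A[, 2, 1] * A[, 3, 2] - A[, 2, 2] * A[, 3, 1]
        det <- A[, 1, 1] * c11 + A[, 1, 2] * c12 + A[, 1, 3] * c13
        # adjugate columns (inverse transpose cofactors)
        i11 <- c11
        i12 <- A[, 1, 3] * A[, 3, 2] - A[, 1, 2] * A[, 3, 3]
        i13 <- A[, 1, 2] * A[, 2, 3] - A[, 1, 3] * A[, 2, 2]
        i21 <- c12
        i22 <- A[, 1, 1] * A[, 3, 3] - A[, 1, 3] * A[, 3, 1]
        i23 <- A[, 1, 3] * A[, 2, 1] - A[, 1, 1] * A[, 2, 3]
        i31 <- c13
        i32 <- A[, 1, 2] * A[, 3, 1] - A[, 1, 1] * A[, 3, 2]
        i33 <- A[, 1, 1] * A[, 2, 2] - A[, 1, 2] * A[, 2, 1]
        delta[, 1] <- -(i11 * G[, 1] + i12 * G[, 2] + i13 * G[, 3]) / det
        delta[, 2] <- -(i21 * G[, 1] + i22 * G[, 2] + i23 * G[, 3]) / det
        delta[, 3] <- -(i31 * G[, 1] + i32 * G[, 2] + i33 * G[, 3]) / det
        bad <- abs(det) < 1e-14
    } else {
        bad <- logical(k)
        for (s in seq_len(k)) {
            As <- matrix(A[s, , ], d, d)
            sol <- tryCatch(solve(As, -G[s, ]), error = function(e) NULL)
            if (is.null(sol)) bad[s] <- TRUE else delta[s, ] <- sol
        }
    }
    # fallback: a plain map step (y + G = F(y)) where Newton is singular
    bad <- bad | !is.finite(rowSums(delta))
    if (any(bad)) delta[bad, ] <- G[bad, , drop = FALSE]
    delta
}

# project chart points back onto the simplex by clipping + renormalization;
# rows that went numerically degenerate restart from the simplex centre
.projectChart <- function(y) {
    X <- pmax(.chartToFull(y), 0)
    tot <- rowSums(X)
    lost <- !is.finite(tot) | tot <= 0
    if (any(lost)) {
        X[lost, ] <- 1 / ncol(X)
        tot[lost] <- 1
    }
    X <- X / tot
    X[, -ncol(X), drop = FALSE]
}

# Damped batched Newton with map-iteration fallback; returns converged
# full-simplex states and a count of dropped starts. Newton runs both from
# the raw starts (which reaches unstable roots and vertices) and from
# relaxed copies that were first iterated under the map itself (which
# reliably reaches attracting interior points whose Newton basin is much
# smaller than their dynamical basin).
.solveFixedPoints <- function(ctx, y0, resTol = 1e-12, maxIter = 60L) {
    yr <- y0
    for (it in seq_len(150L)) yr <- .projectChart(.chartMap(ctx, yr))
    y <- rbind(y0, yr)
    runNewton <- function(y, iters) {
        active <- seq_len(nrow(y))
        for (it in seq_len(iters)) {
            ya <- y[active, , drop = FALSE]
            G <- .chartMap(ctx, ya) - ya
            resA <- apply(abs(G), 1L, max)
            done <- resA < resTol
            if (any(done)) {
                active <- active[!done]
                ya <- ya[!done, , drop = FALSE]
                G <- G[!done, , drop = FALSE]
            }
            if (length(active) == 0L) break
            J <- .chartJacobian(ctx, ya)
            delta <- .newtonStep(J, G)
            # damp oversized steps
            nrm <- sqrt(rowSums(delta^2))
            sc <- pmin(1, 0.5 / pmax(nrm, 1e-300))
            delta <- delta * sc
            y[active, ] <- .projectChart(ya + delta)
        }
        y
    }
    y <- runNewton(y, maxIter)
    G <- .chartMap(ctx, y) - y
    res <- apply(abs(G), 1L, max)
    notOk <- res >= resTol
    if (any(notOk)) {
        # fallback: relax by direct map iteration, then polish again
        ysub <- .projectChart(y[notOk, , drop = FALSE])
        for (it in seq_len(400L)) ysub <- .projectChart(.chartMap(ctx, ysub))
        ysub <- runNewton(ysub, 30L)
        y[notOk, ] <- ysub
        G <- .chartMap(ctx, y) - y
        res <- apply(abs(G), 1L, max)
    }
    ok <- res < resTol
    list(X = .chartToFull(y[ok, , drop = FALSE]), dropped = sum(!ok))
}

.dedupeStates <- function(X, tol = 1e-6) {
    if (nrow(X) == 0L) return(X)
    kept <- X[1L, , drop = FALSE]
    for (i in seq_len(nrow(X))[-1L]) {
        d <- apply(abs(kept - matrix(X[i, ], nrow(kept), ncol(X),
                                     byrow = TRUE)), 1L, max)
        if (all(d > tol)) kept <- rbind(kept, X[i, ])
    }
    kept
}

#' Dirichlet(1) initial conditions on the simplex
#'
#' Uniform sampling of the (N-1)-simplex, used for fixed-point searches and
#' basin-of-attraction estimates. Draws from the current RNG stream.
#'
#' @param n number of draws.
#' @param N number of strains.
#' @return n x N matrix of states, rows summing to 1.
#' @export
rdirichletStarts <- function(n, N) {
    X <- matrix(stats::rexp(n * N), n, N)
    X / rowSums(X)
}

#' Locate fixed points of the replicator map
#'
#' From \code{nInit} Dirichlet(1) starting points, solves F(X) = X on the
#' simplex chart by damped Newton iteration (with clipping back onto the
#' simplex and a direct map-iteration fallback), keeps solutions with
#' residual below 1e-10, deduplicates at sup-norm distance 1e-6, and
#' classifies each fixed point by the spectral radius of the chart Jacobian.
#' The N vertices (single-strain fixation states) are fixed points of the
#' replicator map by construction and are always included, with
#' \code{interior = FALSE}.
#'
#' Stability uses a tiny margin: a point counts as stable only when the
#' spectral radius is below 1 - 1e-9, so floating-point knife edges are
#' reported as unstable. Robustness is 1 minus the spectral radius for
#' stable interior points and 0 otherwise.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @param params a \code{\linkS4class{ModelParams}}.
#' @param nInit number of Dirichlet(1) starts.
#' @param costs realized costs; drawn via \code{\link{realizedCosts}} when
#'   NULL (so jitter follows \code{params@jitterScale}).
#' @param interiorThreshold entries above this count as strictly positive.
#' @return data.frame with columns \code{X1..XN}, \code{residual},
#'   \code{interior}, \code{spectralRadius}, \code{stable},
#'   \code{robustness}; the number of non-convergent starts is attached as
#'   attribute \code{"dropped"}.
#' @export
findFixedPoints <- function(community, params, nInit = 100, costs = NULL,
                            interiorThreshold = 1e-6) {
    N <- nStrains(community)
    if (is.null(costs))
        costs <- realizedCosts(params, nAntibiotics(community))
    r <- growthRates(community, costs, params@g)
    ctx <- .modelContext(community, params, costs)
    if (N == 1L) {
        out <- data.frame(X1 = 1, residual = 0, interior = FALSE,
                          spectralRadius = 0, stable = TRUE, robustness = 0)
        attr(out, "dropped") <- 0L
        return(out)
    }
    y0 <- rdirichletStarts(nInit, N)[, -N, drop = FALSE]
    sol <- .solveFixedPoints(ctx, y0)
    X <- rbind(sol$X, diag(N))
    # keep candidates on (or numerically at) the simplex
    X <- X[apply(X, 1L, function(x) all(x > -1e-9)), , drop = FALSE]
    X[X < 0] <- 0
    X <- X / rowSums(X)
    resid <- apply(abs(.batchMap(ctx, X) - X), 1L, max)
    X <- X[resid < 1e-10, , drop = FALSE]
    X <- .dedupeStates(X, tol = 1e-6)
    n <- nrow(X)
    sr <- numeric(n); res <- numeric(n)
    for (i in seq_len(n)) {
        y <- X[i, -N, drop = FALSE]
        J <- matrix(.chartJacobian(ctx, y)[1L, , ], N - 1L, N - 1L)
        sr[i] <- if (N == 1L) 0 else
            max(abs(eigen(J, only.values = TRUE)$values))
        res[i] <- max(abs(.batchMap(ctx, X[i, , drop = FALSE]) - X[i, ]))
    }
    interior <- apply(X, 1L, function(x) all(x > interiorThreshold))
    stable <- sr < 1 - 1e-9
    robustness <- ifelse(stable & interior, pmax(0, 1 - sr), 0)
    out <- data.frame(X, residual = res, interior = interior,
                      spectralRadius = sr, stable = stable,
                      robustness = robustness)
    names(out)[seq_len(N)] <- paste0("X", seq_len(N))
    attr(out, "dropped") <- sol$dropped
    out
}

#' Spectral radius of the replicator Jacobian at a fixed point
#'
#' Central finite differences (step 1e-7) of the update map in the
#' (N-1)-dimensional simplex chart. The point must satisfy the fixed-point
#' residual contract (sup-norm residual below 1e-10).
#'
#' @param community a \code{\linkS4class{Community}}.
#' @param params a \code{\linkS4class{ModelParams}}.
#' @param Xstar fixed point on the simplex.
#' @param costs realized costs (drawn when NULL; use \code{jitterScale = 0}
#'   for exactly identical costs).
#' @param h finite-difference step.
#' @return nonnegative spectral radius; below 1 means stable (discrete
#'   time).
#' @export
jacobianSpectralRadius <- function(community, params, Xstar, costs = NULL,
                                   h = 1e-7) {
    N <- nStrains(community)
    if (is.null(costs))
        costs <- realizedCosts(params, nAntibiotics(community))
    ctx <- .modelContext(community, params, costs)
    Xs <- matrix(Xstar, nrow = 1L)
    resid <- max(abs(.batchMap(ctx, Xs) - Xs))
    if (resid >= 1e-10)
        stop("Xstar violates the fixed-point residual contract (residual ",
             format(resid), ")")
    if (N == 1L) return(0)
    J <- matrix(.chartJacobian(ctx, Xs[, -N, drop = FALSE], h = h)[1L, , ],
                N - 1L, N - 1L)
    max(abs(eigen(J, only.values = TRUE)$values))
}

#' Basin-of-attraction fraction of stable interior coexistence
#'
#' The fraction of Dirichlet(1)-initialized trajectories whose terminal
#' state lies within \code{matchTol} (sup-norm) of a stable interior fixed
#' point. Communities without a stable interior fixed point score 0 by
#' definition.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @param params a \code{\linkS4class{ModelParams}}.
#' @param nInit number of trajectories.
#' @param costs realized costs shared by the fixed-point search and the
#'   trajectories (drawn once when NULL).
#' @param fixedPoints optional precomputed result of
#'   \code{\link{findFixedPoints}} under the same costs.
#' @param maxSteps,tol trajectory iteration controls.
#' @param matchTol terminal-state matching tolerance.
#' @return fraction in [0, 1].
#' @export
basinFraction <- function(community, params, nInit = 100, costs = NULL,
                          fixedPoints = NULL, maxSteps = 1e5, tol = 1e-13,
                          matchTol = 1e-4) {
    N <- nStrains(community)
    if (is.null(costs))
        costs <- realizedCosts(params, nAntibiotics(community))
    if (is.null(fixedPoints))
        fixedPoints <- findFixedPoints(community, params, nInit = nInit,
                                       costs = costs)
    targets <- fixedPoints[fixedPoints$stable & fixedPoints$interior,
                           seq_len(N), drop = FALSE]
    if (nrow(targets) == 0L) return(0)
    ctx <- .modelContext(community, params, costs)
    X <- rdirichletStarts(nInit, N)
    for (it in seq_len(maxSteps)) {
        Xn <- .batchMap(ctx, X)
        done <- max(abs(Xn - X)) < tol
        X <- Xn
        if (done) break
    }
    hit <- vapply(seq_len(nrow(X)), function(s) {
        any(apply(abs(t(targets) - X[s, ]), 2L, max) < matchTol)
    }, TRUE)
    mean(hit)
}
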