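#' Exhaustive stability survey over a community catalogue
#'
#' For every unique community with N strains and M antibiotics, searches
#' for fixed points of the replicator dynamics at the given parameter
#' combination and records how many stable interior (full-coexistence)
#' fixed points exist, together with the basin-of-attraction fraction and
#' the structural descriptors. Surveys keep the per-antibiotic cost jitter
#' on (it removes degeneracies that exist only at exactly identical costs);
#' each community draws from its own seed substream derived from the master
#' seed and its canonical notation, so results are independent of execution
#' order and of which other communities are surveyed.
#'
#' Communities containing a strain whose phenotype costs consume its whole
#' growth rate are not viable as stated and are recorded with zero stable
#' fixed points and \code{viable = FALSE}.
#'
#' @param N,M strain and antibiotic counts (catalogue is enumerated unless
#'   supplied).
#' @param combo a \code{\linkS4class{ModelParams}} or a label accepted by
#'   \code{\link{parameterCombination}}.
#' @param nInit Dirichlet(1) starts per community.
#' @param seed master seed.
#' @param catalogue optional precomputed
#'   \code{\linkS4class{CommunityCatalogue}}.
#' @param computeBasin also estimate the basin fraction for communities
#'   with a stable interior fixed point (others are 0 by definition).
#' @return data.frame with one row per catalogue member: \code{community},
#'   \code{combo}, \code{n_stable_interior}, \code{basin_fraction},
#'   \code{psd_coverage}, \code{cyclicity}, \code{viable}.
#' @export
surveyTopologies <- function(N, M, combo = "low_cost", nInit = 100,
                             seed = 1L, catalogue = NULL,
                             computeBasin = TRUE) {
    params <- if (is(combo, "ModelParams")) combo
              else parameterCombination(combo)
    label <- if (is.character(combo)) combo else "custom"
    if (is.null(catalogue)) catalogue <- enumerateCommunities(N, M)
    notations <- members(catalogue)
    n <- length(notations)
    nStable <- integer(n)
    basin <- numeric(n)
    viable <- logical(n)
    psd <- integer(n)
    cyc <- integer(n)
    for (i in seq_len(n)) {
        comm <- parseCommunity(notations[i])
        psd[i] <- psdCoverage(comm)
        cyc[i] <- cyclicity(comm)
        set.seed(.substreamSeed(seed, notations[i]))
        costs <- realizedCosts(params, M)
        r <- .growthRatesRaw(comm, costs, params@g)
        if (any(r <= 0)) {
            viable[i] <- FALSE
            next
        }
        viable[i] <- TRUE
        fp <- findFixedPoints(comm, params, nInit = nInit, costs = costs)
        nStable[i] <- sum(fp$stable & fp$interior)
        if (nStable[i] > 0L && computeBasin)
            basin[i] <- basinFraction(comm, params, nInit = nInit,
                                      costs = costs, fixedPoints = fp)
    }
    data.frame(community = notations, combo = label,
               n_stable_interior = nStable, basin_fraction = basin,
               psd_coverage = psd, cyclicity = cyc, viable = viable,
               row.names = NULL)
}

#' Classify stable communities by motif structure
#'
#' Assigns each stable community from an (N = 3, M = 3) survey to one of
#' the four categories observed among coexisting topologies:
#' \describe{
#'   \item{\code{circulant-3PSD}}{the fully circulant community with three
#'     PSD motifs (\code{[PDS,SPD,DSP]}).}
#'   \item{\code{acirculant-3PSD}}{three PSD motifs not arranged in a fully
#'     cyclic pattern.}
#'   \item{\code{extension-of-2PSD-circulant}}{reduces to the circulant
#'     two-PSD community \code{[PD,SP,DS]} on deleting one antibiotic.}
#'   \item{\code{extension-of-PDSPRS}}{reduces to the near-circulant
#'     community \code{[PD,SP,RS]} on deleting one antibiotic.}
#' }
#' Anything else is \code{other}. Precedence follows the list order, so a
#' three-PSD community that is also an extension is reported by its PSD
#' coverage, matching the published four-category scheme.
#'
#' @param records a survey data.frame from \code{\link{surveyTopologies}}
#'   (rows with \code{n_stable_interior >= 1} are classified), or a
#'   character vector of community notations.
#' @return named integer tally over the five categories, with the
#'   per-community assignments attached as attribute \code{"assignments"}.
#' @export
classifyStable <- function(records) {
    notations <- if (is.data.frame(records))
        records$community[records$n_stable_interior >= 1L]
    else as.character(records)
    circ2 <- Community("[PD,SP,DS]")
    nearCirc <- Community("[PD,SP,RS]")
    cats <- c("circulant-3PSD", "acirculant-3PSD",
              "extension-of-2PSD-circulant", "extension-of-PDSPRS", "other")
    assign <- vapply(notations, function(s) {
        comm <- parseCommunity(s)
        M <- nAntibiotics(comm)
        psd <- psdCoverage(comm)
        cyc <- cyclicity(comm)
        if (psd == 3L && cyc == M) "circulant-3PSD"
        else if (psd == 3L) "acirculant-3PSD"
        else if (M > 2L && isExtension(comm, circ2))
            "extension-of-2PSD-circulant"
        else if (M > 2L && isExtension(comm, nearCirc))
            "extension-of-PDSPRS"
        else "other"
    }, character(1))
    tally <- stats::setNames(integer(length(cats)), cats)
    tb <- table(assign)
    tally[names(tb)] <- as.integer(tb)
    attr(tally, "assignments") <- data.frame(community = notations,
                                             category = unname(assign),
                                             row.names = NULL)
    tally
}

# Evaluate one stability metric for a community at exactly identical costs
# (jitter off), as used by the comparison sweeps.
.metricAt <- function(community, params, metric, nInit) {
    M <- nAntibiotics(community)
    costs <- list(crJ = rep(params@cr, M), cdJ = rep(params@cd, M),
                  cpJ = rep(params@cp, M))
    r <- .growthRatesRaw(community, costs, params@g)
    if (any(r <= 0)) return(0)
    fp <- findFixedPoints(community, params, nInit = nInit, costs = costs)
    sel <- fp$stable & fp$interior
    if (!any(sel)) return(0)
    if (metric == "robustness") return(max(fp$robustness[sel]))
    basinFraction(community, params, nInit = nInit, costs = costs,
                  fixedPoints = fp)
}

#' Sweep stability metrics over a metabolic-cost grid
#'
#' Fixes cr and varies the relative costs cp/cr and cd/cr, evaluating
#' either the basin-of-attraction fraction or the robustness (1 minus the
#' Jacobian spectral radius at the stable interior fixed point; 0 when no
#' such point exists). Costs are exactly identical across antibiotics in
#' sweeps, so the comparison isolates the interaction graph.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @param base base parameters (a \code{\linkS4class{ModelParams}} or
#'   label); cr, g, and the strengths are taken from it unless overridden.
#' @param cpRatios,cdRatios grids of cp/cr and cd/cr.
#' @param KP,KD optional strength overrides.
#' @param metric \code{"basin_fraction"} or \code{"robustness"}.
#' @param nInit Dirichlet(1) starts per grid point.
#' @param seed master seed; every grid point gets its own substream.
#' @return numeric matrix (length(cpRatios) x length(cdRatios)) with the
#'   ratio grids as dimnames.
#' @export
sweepCostGrid <- function(community, base = "low_cost",
                          cpRatios = seq(1, 4, length.out = 41),
                          cdRatios = seq(1, 3, length.out = 41),
                          KP = NULL, KD = NULL,
                          metric = c("basin_fraction", "robustness"),
                          nInit = 100, seed = 1L) {
    metric <- match.arg(metric)
    base <- if (is(base, "ModelParams")) base
            else parameterCombination(base, jitterScale = 0)
    out <- matrix(NA_real_, length(cpRatios), length(cdRatios),
                  dimnames = list(signif(cpRatios, 6), signif(cdRatios, 6)))
    for (a in seq_along(cpRatios)) for (b in seq_along(cdRatios)) {
        params <- suppressWarnings(modelParams(
            g = base@g, cr = base@cr,
            cd = cdRatios[b] * base@cr, cp = cpRatios[a] * base@cr,
            KP = if (is.null(KP)) base@KP else KP,
            KD = if (is.null(KD)) base@KD else KD,
            jitterScale = 0))
        set.seed(.substreamSeed(seed, sprintf("cost|%d|%d", a, b)))
        out[a, b] <- .metricAt(community, params, metric, nInit)
    }
    out
}

#' Sweep stability metrics over an antibiotic/degrader strength grid
#'
#' As \code{\link{sweepCostGrid}}, but varying the strengths KP and KD at
#' fixed cost ratios.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @param base base parameters (costs are taken from it).
#' @param KPgrid,KDgrid strength grids.
#' @param metric,nInit,seed as in \code{\link{sweepCostGrid}}.
#' @return numeric matrix (length(KPgrid) x length(KDgrid)).
#' @export
sweepStrengthGrid <- function(community, base = "low_cost",
                              KPgrid = c(10, 40), KDgrid = c(2, 10),
                              metric = c("basin_fraction", "robustness"),
                              nInit = 100, seed = 1L) {
    metric <- match.arg(metric)
    base <- if (is(base, "ModelParams")) base
            else parameterCombination(base, jitterScale = 0)
    out <- matrix(NA_real_, length(KPgrid), length(KDgrid),
                  dimnames = list(signif(KPgrid, 6), signif(KDgrid, 6)))
    for (a in seq_along(KPgrid)) for (b in seq_along(KDgrid)) {
        params <- suppressWarnings(modelParams(
            g = base@g, cr = base@cr, cd = base@cd, cp = base@cp,
            KP = KPgrid[a], KD = KDgrid[b], jitterScale = 0))
        set.seed(.substreamSeed(seed, sprintf("strength|%d|%d", a, b)))
        out[a, b] <- .metricAt(community, params, metric, nInit)
    }
    out
}
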