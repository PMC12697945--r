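#' @import methods
NULL

PHENOTYPES <- c("P", "S", "D", "R")

#' Community: an antibiotic-mediated interaction graph
#'
#' An N x M matrix of discrete phenotypes describing how each of N strains
#' relates to each of M antibiotics: producer (\code{P}), sensitive
#' (\code{S}), degrader (\code{D}) or intrinsically resistant (\code{R}).
#' Rows are strains, columns are antibiotics. Communities are considered
#' identical up to simultaneous relabelling of strains (row permutation) and
#' antibiotics (column permutation); see \code{\link{canonicalForm}}.
#'
#' @slot phenotypes character matrix with entries in \code{P,S,D,R}.
#'
#' @seealso \code{\link{parseCommunity}}, \code{\link{psdCoverage}},
#'   \code{\link{cyclicity}}, \code{\link{isExtension}}
#' @export
setClass("Community", representation(phenotypes = "matrix"))

setValidity("Community", function(object) {
    m <- object@phenotypes
    if (!is.character(m) || length(dim(m)) != 2L)
        return("phenotypes must be a character matrix")
    if (nrow(m) < 1L || ncol(m) < 1L)
        return("community needs at least one strain and one antibiotic")
    bad <- !(m %in% PHENOTYPES)
    if (any(bad))
        return(sprintf("illegal phenotype symbol(s): %s",
                       paste(unique(m[bad]), collapse = ", ")))
    TRUE
})

#' Construct a Community from a phenotype matrix
#'
#' @param phenotypes character matrix over \code{P,S,D,R}, or a notation
#'   string such as \code{"[PD,SP,DS]"} (forwarded to
#'   \code{\link{parseCommunity}}).
#' @return a \code{\linkS4class{Community}}.
#' @examples
#' Community(matrix(c("P","S","D"), ncol = 1))
#' Community("[PD,SP,DS]")
#' @export
Community <- function(phenotypes) {
    if (is.character(phenotypes) && is.null(dim(phenotypes)) &&
        length(phenotypes) == 1L)
        return(parseCommunity(phenotypes))
    dimnames(phenotypes) <- NULL
    new("Community", phenotypes = phenotypes)
}

#' CommunityCatalogue: all unique communities for a given (N, M)
#'
#' The ordered result of exhaustively enumerating the equivalence classes
#' (up to strain and antibiotic permutation) of N x M phenotype matrices,
#' filtered by a configurable redundancy-rule set. Members are stored as
#' canonical notation strings and are pairwise non-equivalent; ordering is
#' lexicographic in the canonical string, so generation is reproducible.
#'
#' @slot N,M integer strain and antibiotic counts.
#' @slot members character vector of canonical notation strings.
#' @slot rules character vector naming the redundancy rules applied
#'   (provenance).
#' @seealso \code{\link{enumerateCommunities}}
#' @export
setClass("CommunityCatalogue",
         representation(N = "integer", M = "integer",
                        members = "character", rules = "character"))

setValidity("CommunityCatalogue", function(object) {
    if (length(object@N) != 1L || length(object@M) != 1L ||
        object@N < 1L || object@M < 1L)
        return("N and M must be single positive integers")
    if (anyDuplicated(object@members))
        return("catalogue members must be pairwise distinct canonical forms")
    TRUE
})

#' ModelParams: parameters of the mixed-inhibition zone model
#'
#' @slot g base growth rate per generation (all strains).
#' @slot cr,cd,cp metabolic costs of intrinsic resistance, degradation and
#'   production, in growth-rate units per antibiotic carried.
#' @slot KP,KD effective killing area per producer and effective degradation
#'   area per degrader (dimensionless products with strain frequencies inside
#'   the exponential kill terms).
#' @slot jitterScale half-width of the per-antibiotic uniform perturbation of
#'   the realized cost of resistance (0 disables the jitter).
#' @seealso \code{\link{modelParams}}, \code{\link{parameterCombination}}
#' @export
setClass("ModelParams",
         representation(g = "numeric", cr = "numeric", cd = "numeric",
                        cp = "numeric", KP = "numeric", KD = "numeric",
                        jitterScale = "numeric"))

setValidity("ModelParams", function(object) {
    for (s in c("g", "cr", "cd", "cp", "KP", "KD", "jitterScale"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            return(sprintf("%s must be a single finite number", s))
    if (object@g <= 0) return("g must be positive")
    if (object@KP < 0 || object@KD < 0)
        return("KP and KD must be nonnegative")
    if (object@jitterScale < 0) return("jitterScale must be nonnegative")
    TRUE
})

#' SpatialParams: parameters of the stochastic hexagonal-lattice model
#'
#' @slot g birth probability scale; \code{d} baseline death probability.
#' @slot d baseline per-generation death probability.
#' @slot cr,cd,cp metabolic costs subtracted from \code{g} per phenotype
#'   carried (as in the well-mixed growth rates).
#' @slot KP,KD diffusivities of the antibiotic and of the degrader enzyme
#'   (squared lattice units per generation; they set the spread of the
#'   secretion kernels).
#' @slot up,ud amount of antibiotic / enzyme secreted per individual per
#'   generation (concentration units at the kernel).
#' @slot gridSize lattice side length (the torus has gridSize^2 sites).
#' @slot pInit initial independent occupancy probability per site.
#' @slot generations,replicates default run length and replicate count.
#' @seealso \code{\link{spatialParams}}, \code{\link{runSpatial}}
#' @export
setClass("SpatialParams",
         representation(g = "numeric", d = "numeric", cr = "numeric",
                        cd = "numeric", cp = "numeric", KP = "numeric",
                        KD = "numeric", up = "numeric", ud = "numeric",
                        gridSize = "integer", pInit = "numeric",
                        generations = "integer", replicates = "integer"))

setValidity("SpatialParams", function(object) {
    if (object@d < 0 || object@d > 1)
        return("d must lie in [0, 1]")
    if (object@pInit < 0 || object@pInit > 1)
        return("pInit must lie in [0, 1]")
    if (object@gridSize < 2L) return("gridSize must be at least 2")
    if (object@KP < 0 || object@KD < 0)
        return("KP and KD must be nonnegative")
    if (object@up < 0 || object@ud < 0)
        return("up and ud must be nonnegative")
    TRUE
})

#' LatticeState: occupancy and chemical fields of the spatial model
#'
#' Axial-coordinate rhombic torus of \code{gridSize^2} hexagonal sites.
#' \code{occupancy} holds 0 for an empty site or the strain index 1..N;
#' chemical fields are recomputed from scratch every generation
#' (quasi-static approximation).
#'
#' @slot occupancy integer matrix (gridSize x gridSize).
#' @slot antibioticFields list of M numeric matrices (one per antibiotic).
#' @slot enzymeFields list of M numeric matrices (degrader enzyme).
#' @slot generation integer generation counter.
#' @slot birthGeneration integer matrix recording each occupant's birth
#'   generation (newborns are skipped in their birth generation).
#' @export
setClass("LatticeState",
         representation(occupancy = "matrix", antibioticFields = "list",
                        enzymeFields = "list", generation = "integer",
                        birthGeneration = "matrix"))

setValidity("LatticeState", function(object) {
    occ <- object@occupancy
    if (!is.numeric(occ) && !is.integer(occ))
        return("occupancy must be an integer matrix")
    if (any(occ < 0)) return("occupancy entries must be >= 0")
    if (any(vapply(object@antibioticFields, function(f) any(f < 0), TRUE)))
        return("antibiotic fields must be entrywise nonnegative")
    if (any(vapply(object@enzymeFields, function(f) any(f < 0), TRUE)))
        return("enzyme fields must be entrywise nonnegative")
    TRUE
})

setMethod("show", "Community", function(object) {
    m <- object@phenotypes
    cat(sprintf("Community: %d strain(s) x %d antibiotic(s)  %s\n",
                nrow(m), ncol(m), formatCommunity(object)))
    cat(sprintf("  PSD coverage %d, cyclicity %d\n",
                psdCoverage(object), cyclicity(object)))
})

setMethod("show", "CommunityCatalogue", function(object) {
    cat(sprintf("CommunityCatalogue: %d communities with N=%d, M=%d\n",
                length(object@members), object@N, object@M))
    cat(sprintf("  rules: %s\n", paste(object@rules, collapse = ", ")))
    k <- min(5L, length(object@members))
    if (k > 0L)
        cat("  ", paste(object@members[seq_len(k)], collapse = " "),
            if (length(object@members) > k) "..." else "", "\n")
})

setMethod("show", "ModelParams", function(object) {
    cat(sprintf(paste0("ModelParams: g=%g cr=%g cd=%g cp=%g ",
                       "KP=%g KD=%g jitter=%g\n"),
                object@g, object@cr, object@cd, object@cp,
                object@KP, object@KD, object@jitterScale))
})

setMethod("show", "SpatialParams", function(object) {
    cat(sprintf(paste0("SpatialParams: g=%g d=%g cr=%g cd=%g cp=%g KP=%g ",
                       "KD=%g up=%g ud=%g grid=%d pInit=%g\n"),
                object@g, object@d, object@cr, object@cd, object@cp,
                object@KP, object@KD, object@up, object@ud,
                object@gridSize, object@pInit))
})

setMethod("show", "LatticeState", function(object) {
    occ <- object@occupancy
    cat(sprintf("LatticeState: %dx%d hexagonal torus, generation %d\n",
                nrow(occ), ncol(occ), object@generation))
    cat(sprintf("  occupied fraction %.3f\n", mean(occ > 0)))
})

#' @describeIn Community-class number of strains (rows)
#' @param x a \code{Community}
#' @export
nStrains <- function(x) nrow(x@phenotypes)

#' @describeIn Community-class number of antibiotics (columns)
#' @export
nAntibiotics <- function(x) ncol(x@phenotypes)

#' @describeIn Community-class the underlying character matrix
#' @export
phenotypeMatrix <- function(x) x@phenotypes

#' Catalogue members
#'
#' @param x a \code{\linkS4class{CommunityCatalogue}}
#' @return character vector of canonical notation strings.
#' @export
members <- function(x) x@members

#' @export
setMethod("length", "CommunityCatalogue", function(x) length(x@members))

#' @export
setMethod("[[", "CommunityCatalogue", function(x, i) {
    parseCommunity(x@members[[i]])
})
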