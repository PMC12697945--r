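# Phenotype symbols are ordered P < S < D < R throughout: this fixed order
# defines lexicographic comparison of matrices and hence canonical forms.
.CODE <- stats::setNames(0:3, c("P", "S", "D", "R"))

.encode <- function(m) {
    matrix(.CODE[m], nrow = nrow(m), ncol = ncol(m))
}

.decode <- function(im) {
    matrix(names(.CODE)[im + 1L], nrow = nrow(im), ncol = ncol(im))
}

# all permutations of seq_len(n), one per row
.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- seq_len(n)[-k]
        cbind(k, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
    }))
}

# lexicographic value of each row of an integer-coded matrix (base 4)
.rowCodes <- function(im) {
    as.vector(im %*% 4^(rev(seq_len(ncol(im))) - 1L))
}

# canonical integer matrix: minimum over column permutations of the
# row-sorted matrix, compared row-major with P<S<D<R
.canonInt <- function(im) {
    M <- ncol(im)
    perms <- .permutations(M)
    best <- NULL
    bestKey <- NULL
    for (p in seq_len(nrow(perms))) {
        cand <- im[, perms[p, ], drop = FALSE]
        codes <- .rowCodes(cand)
        o <- order(codes)
        key <- codes[o]
        if (is.null(bestKey) || .lexLess(key, bestKey)) {
            best <- cand[o, , drop = FALSE]
            bestKey <- key
        }
    }
    best
}

.lexLess <- function(a, b) {
    d <- a - b
    i <- which(d != 0)
    length(i) > 0 && d[i[1]] < 0
}

#' Parse a community notation string
#'
#' Communities are written as a bracketed, comma-separated list of rows, one
#' per strain; the j-th letter of a row is the strain's phenotype with
#' respect to the j-th antibiotic, e.g. \code{"[PD,SP,DS]"}. Whitespace
#' around rows is permitted.
#'
#' @param text notation string.
#' @return a \code{\linkS4class{Community}}.
#' @examples
#' parseCommunity("[PDS, SPD, DSP]")
#' @export
parseCommunity <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    s <- trimws(text)
    if (!startsWith(s, "[") || !endsWith(s, "]"))
        stop("community notation must be wrapped in brackets: ", text)
    body <- substr(s, 2L, nchar(s) - 1L)
    rows <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
    if (length(rows) == 0L || all(!nzchar(rows)))
        stop("empty community list: ", text)
    if (any(!nzchar(rows)))
        stop("empty row at position ", which(!nzchar(rows))[1], " in ", text)
    lens <- nchar(rows)
    if (length(unique(lens)) != 1L)
        stop("ragged row lengths: row ", which(lens != lens[1])[1],
             " ('", rows[which(lens != lens[1])[1]], "') has length ",
             lens[lens != lens[1]][1], ", expected ", lens[1])
    chars <- strsplit(rows, "", fixed = TRUE)
    for (i in seq_along(chars)) {
        bad <- setdiff(chars[[i]], names(.CODE))
        if (length(bad))
            stop("illegal phenotype letter '", bad[1], "' in row ", i,
                 " ('", rows[i], "'); allowed letters are P, S, D, R")
    }
    Community(do.call(rbind, chars))
}

#' Format a community as its notation string
#'
#' Inverse of \code{\link{parseCommunity}}: rows joined by commas inside
#' brackets.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @return notation string, e.g. \code{"[PD,SP,DS]"}.
#' @export
formatCommunity <- function(community) {
    m <- community@phenotypes
    paste0("[", paste(apply(m, 1L, paste, collapse = ""), collapse = ","),
           "]")
}

#' Indicator matrices of the four phenotypes
#'
#' @param community a \code{\linkS4class{Community}}.
#' @return named list of four 0/1 matrices \code{P}, \code{S}, \code{D},
#'   \code{R} that partition the cells (their sum is the all-ones matrix).
#' @export
indicatorMatrices <- function(community) {
    m <- community@phenotypes
    lapply(stats::setNames(nm = names(.CODE)), function(ph) {
        (m == ph) + 0
    })
}

#' PSD motif coverage
#'
#' The number of antibiotics (columns) for which the community carries a
#' full producer-sensitive-degrader motif: at least one P, one S and one D
#' entry in that column. The PSD motif is the higher-order structure in
#' which a degrader attenuates the producer-sensitive interaction.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @return integer count in \code{0..M}.
#' @examples
#' psdCoverage(Community("[PD,SP,DS]")) # 2
#' psdCoverage(Community("[PD,SP,RS]")) # 1
#' @export
psdCoverage <- function(community) {
    m <- community@phenotypes
    sum(apply(m, 2L, function(col) {
        all(c("P", "S", "D") %in% col)
    }))
}

.rotDown <- function(x) c(x[length(x)], x[-length(x)])

#' Cyclicity of the interaction matrix
#'
#' The largest number k of columns that form a circulant block under some
#' ordering of the strains: each successive column equals the previous one
#' rotated one element downward. Because communities are defined only up to
#' strain permutation, the measure is maximized over row orderings; a single
#' column is vacuously circulant, so the result is always at least 1.
#' Rotation by one element upward gives the same measure (the columns can be
#' reordered), which is asserted in the test suite.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @return integer in \code{1..M}.
#' @examples
#' cyclicity(Community("[PDS,SPD,DSP]")) # 3
#' cyclicity(Community("[PD,SP,DS]"))    # 2
#' @export
cyclicity <- function(community) {
    im <- .encode(community@phenotypes)
    N <- nrow(im); M <- ncol(im)
    if (M == 1L) return(1L)
    best <- 1L
    rperms <- .permutations(N)
    for (p in seq_len(nrow(rperms))) {
        mm <- im[rperms[p, ], , drop = FALSE]
        cols <- lapply(seq_len(M), function(j) mm[, j])
        # edge j -> l if column l is column j rotated one element downward
        adj <- vector("list", M)
        for (j in seq_len(M)) {
            rj <- .rotDown(cols[[j]])
            adj[[j]] <- which(vapply(cols, function(cl) all(cl == rj), TRUE))
        }
        longest <- function(j, visited) {
            visited[j] <- TRUE
            ext <- 0L
            for (l in adj[[j]]) if (!visited[l])
                ext <- max(ext, longest(l, visited))
            1L + ext
        }
        for (j in seq_len(M)) {
            best <- max(best, longest(j, rep(FALSE, M)))
            if (best == M) return(best)
        }
    }
    best
}

#' Canonical form of a community
#'
#' The lexicographically minimal phenotype matrix over all row and column
#' permutations, with the fixed letter order P < S < D < R and row-major
#' comparison. Two communities describe the same interaction graph (up to
#' strain and antibiotic relabelling) exactly when their canonical forms are
#' identical; the operation is idempotent.
#'
#' @param community a \code{\linkS4class{Community}}.
#' @return the canonical \code{\linkS4class{Community}}.
#' @export
canonicalForm <- function(community) {
    Community(.decode(.canonInt(.encode(community@phenotypes))))
}

#' @rdname canonicalForm
#' @return \code{canonicalNotation}: the canonical form's notation string,
#'   usable as a dictionary key for equivalence classes.
#' @export
canonicalNotation <- function(community) {
    formatCommunity(canonicalForm(community))
}

#' Is one community an extension of another?
#'
#' A community \code{child} is an extension of \code{parent} when its
#' interaction graph equals that of \code{parent} plus interactions via
#' additional antibiotics: \code{child} has the same strains, strictly more
#' antibiotics, and some subset of its columns of size \code{M(parent)} is
#' equivalent (same canonical form) to \code{parent}.
#'
#' @param child,parent \code{\linkS4class{Community}} objects with equal
#'   strain counts.
#' @return logical flag.
#' @examples
#' isExtension(Community("[PDS,SPD,DSP]"), Community("[PD,SP,DS]")) # TRUE
#' @export
isExtension <- function(child, parent) {
    if (nStrains(child) != nStrains(parent))
        stop("strain-count mismatch: child has ", nStrains(child),
             " strains, parent has ", nStrains(parent))
    Mc <- nAntibiotics(child)
    Mp <- nAntibiotics(parent)
    if (Mc <= Mp) return(FALSE)
    target <- canonicalNotation(parent)
    subsets <- utils::combn(Mc, Mp, simplify = FALSE)
    for (cols in subsets) {
        sub <- Community(child@phenotypes[, cols, drop = FALSE])
        if (canonicalNotation(sub) == target) return(TRUE)
    }
    FALSE
}
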