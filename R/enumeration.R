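#' Unsigned Stirling numbers of the first kind
#'
#' s(n, k): the number of permutations of n elements with exactly k cycles,
#' computed by the recurrence s(n, k) = s(n-1, k-1) + (n-1) s(n-1, k).
#'
#' @param n,k nonnegative integers with \code{k <= n}.
#' @return the count as a numeric (exact for the sizes used here).
#' @examples
#' stirlingFirst(4, 2) # 11
#' @export
stirlingFirst <- function(n, k) {
    if (n < 0 || k < 0) stop("negative arguments to stirlingFirst")
    if (k > n) stop("k must not exceed n")
    tab <- matrix(0, n + 1L, n + 1L)
    tab[1L, 1L] <- 1
    for (nn in seq_len(n)) {
        for (kk in seq_len(nn)) {
            tab[nn + 1L, kk + 1L] <- tab[nn, kk] + (nn - 1) * tab[nn, kk + 1L]
        }
    }
    tab[n + 1L, k + 1L]
}

#' Closed-form count of interaction graphs
#'
#' Evaluates the cycle-index style counting expression
#' \deqn{\frac{1}{N!\,M!}\sum_{i=0}^{N}\sum_{j=0}^{M} s(N,i)\,s(M,j)\,4^{ij}}
#' with unsigned Stirling numbers of the first kind. The value is returned
#' exactly as the formula gives it, without rounding: it is not an integer
#' in general and differs from the exhaustive orbit count (the exact Burnside
#' count involves gcds of cycle lengths, not products of cycle counts), so it
#' is reported alongside, never used as a check on, enumeration results.
#'
#' @param N,M positive integers (at most 5; beyond that the powers of four
#'   exceed exact double-precision integers).
#' @return numeric value, possibly non-integer.
#' @examples
#' countFormula(2, 2) # 73
#' @export
countFormula <- function(N, M) {
    stopifnot(N >= 1, M >= 1)
    if (N > 5 || M > 5) stop("countFormula supports N, M <= 5 only")
    total <- 0
    for (i in 0:N) for (j in 0:M) {
        total <- total + stirlingFirst(N, i) * stirlingFirst(M, j) * 4^(i * j)
    }
    total / (factorial(N) * factorial(M))
}

# decode row code 0..4^M-1 into M base-4 digits (most significant first)
.codeDigits <- function(codes, M) {
    d <- matrix(0L, length(codes), M)
    for (j in seq_len(M)) {
        pw <- 4^(M - j)
        d[, j] <- (codes %/% pw) %% 4L
    }
    d
}

# sort each row of a small-N integer matrix with a compare-swap network
.sortRows <- function(m) {
    cs <- function(m, i, j) {
        lo <- pmin(m[, i], m[, j]); hi <- pmax(m[, i], m[, j])
        m[, i] <- lo; m[, j] <- hi
        m
    }
    n <- ncol(m)
    if (n == 1L) return(m)
    if (n == 2L) return(cs(m, 1L, 2L))
    if (n == 3L) return(cs(cs(cs(m, 1L, 2L), 2L, 3L), 1L, 2L))
    if (n == 4L) {
        m <- cs(m, 1L, 2L); m <- cs(m, 3L, 4L)
        m <- cs(m, 1L, 3L); m <- cs(m, 2L, 4L)
        return(cs(m, 2L, 3L))
    }
    t(apply(m, 1L, sort))
}

#' Enumerate all unique communities for given N and M
#'
#' Exhaustively generates every equivalence class, up to strain (row) and
#' antibiotic (column) relabelling, of N x M phenotype matrices over
#' \code{P, S, D, R}, filtered by a configurable redundancy-rule set:
#' \describe{
#'   \item{\code{distinctStrains}}{drop matrices with duplicated rows (two
#'     identical strains are one strain).}
#'   \item{\code{distinctAntibiotics}}{drop matrices with duplicated columns
#'     (two antibiotics with identical phenotype patterns act as one).}
#' }
#' Under the default rule set the catalogue sizes match the published
#' community counts (6 for N=2, M=1; 6864 for N=3, M=3). The catalogue is
#' ordered lexicographically by canonical notation, so generation is
#' bit-reproducible.
#'
#' @param N,M strain and antibiotic counts (each at most 5, and the raw
#'   combination count must stay enumerable).
#' @param rules character vector of redundancy rules to apply.
#' @return a \code{\linkS4class{CommunityCatalogue}}.
#' @examples
#' length(enumerateCommunities(2, 1)) # 6
#' @export
enumerateCommunities <- function(N, M,
                                 rules = c("distinctStrains",
                                           "distinctAntibiotics")) {
    stopifnot(N >= 1, M >= 1)
    if (N > 5 || M > 5)
        stop("enumeration guard: N and M must both be at most 5")
    unknown <- setdiff(rules, c("distinctStrains", "distinctAntibiotics"))
    if (length(unknown))
        stop("unknown redundancy rule(s): ", paste(unknown, collapse = ", "))
    A <- 4^M
    distinctRows <- "distinctStrains" %in% rules
    nRaw <- if (distinctRows) choose(A, N) else choose(A + N - 1, N)
    if (nRaw > 3e6)
        stop("enumeration guard: ", format(nRaw, big.mark = ","),
             " row combinations exceed the enumerable limit for N=", N,
             ", M=", M)
    # communities as sorted N-tuples of row codes (0 .. 4^M - 1)
    if (distinctRows) {
        combos <- utils::combn(A, N) - 1L
    } else {
        combos <- utils::combn(A + N - 1L, N) - 1L
        combos <- combos - (seq_len(N) - 1L)  # multiset combinations
    }
    tup <- t(combos)                         # k x N, ascending codes
    # canonical key = min over column permutations of the sorted row codes,
    # packed in base 4^M (row-major comparison with P<S<D<R fixed order)
    perms <- .permutations(M)
    digitsAll <- .codeDigits(0:(A - 1L), M)
    weights <- 4^(rev(seq_len(M)) - 1L)
    key <- NULL
    packW <- A^(rev(seq_len(N)) - 1L)
    for (p in seq_len(nrow(perms))) {
        remap <- as.integer(digitsAll[, perms[p, ], drop = FALSE] %*% weights)
        cand <- matrix(remap[tup + 1L], nrow(tup), N)
        cand <- .sortRows(cand)
        k <- as.vector(cand %*% packW)
        key <- if (is.null(key)) k else pmin(key, k)
    }
    reps <- sort(unique(key))
    # unpack canonical keys back into row codes
    repRows <- matrix(0, length(reps), N)
    rem <- reps
    for (i in seq_len(N)) {
        repRows[, i] <- rem %/% packW[i]
        rem <- rem %% packW[i]
    }
    if ("distinctAntibiotics" %in% rules && M > 1L) {
        keep <- vapply(seq_len(nrow(repRows)), function(i) {
            dg <- .codeDigits(repRows[i, ], M)   # N x M phenotype digits
            !anyDuplicated(t(dg))
        }, TRUE)
        repRows <- repRows[keep, , drop = FALSE]
    }
    notation <- vapply(seq_len(nrow(repRows)), function(i) {
        dg <- .codeDigits(repRows[i, ], M)
        formatCommunity(Community(.decode(dg)))
    }, character(1))
    new("CommunityCatalogue", N = as.integer(N), M = as.integer(M),
        members = notation, rules = as.character(rules))
}

#' Export a catalogue to CSV with a JSON sidecar
#'
#' Writes one row per community with its canonical notation and structural
#' descriptors, plus \code{<file>.json} recording N, M, the rule set, the
#' package version and the member count.
#'
#' @param catalogue a \code{\linkS4class{CommunityCatalogue}}.
#' @param file output CSV path.
#' @return the CSV path, invisibly.
#' @export
exportCatalogue <- function(catalogue, file) {
    df <- data.frame(
        index = seq_along(catalogue@members),
        canonical_notation = catalogue@members,
        N = catalogue@N, M = catalogue@M,
        psd_coverage = vapply(catalogue@members,
                              function(s) psdCoverage(parseCommunity(s)), 0L),
        cyclicity = vapply(catalogue@members,
                           function(s) cyclicity(parseCommunity(s)), 0L),
        row.names = NULL)
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    meta <- list(N = catalogue@N, M = catalogue@M,
                 rules = as.list(catalogue@rules),
                 tool_version = as.character(utils::packageVersion("AMICoex")),
                 count = length(catalogue@members))
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
    invisible(file)
}
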