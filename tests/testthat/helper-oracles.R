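# Independent brute-force oracles used to derive expected values. These are
# deliberately naive implementations, kept separate from the package's own
# algorithms.

# all permutations of 1..n via recursive insertion
oraclePermList <- function(n) {
    if (n == 1L) return(list(1L))
    smaller <- oraclePermList(n - 1L)
    out <- list()
    for (p in smaller) for (pos in 0:(n - 1L)) {
        out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
    out
}

# unsigned Stirling numbers of the first kind by counting cycles of every
# permutation of n elements
oracleStirling <- function(n, k) {
    if (n == 0L) return(as.numeric(k == 0L))
    count <- 0L
    for (p in oraclePermList(n)) {
        seen <- rep(FALSE, n)
        cycles <- 0L
        for (i in seq_len(n)) {
            if (!seen[i]) {
                cycles <- cycles + 1L
                j <- i
                while (!seen[j]) {
                    seen[j] <- TRUE
                    j <- p[j]
                }
            }
        }
        if (cycles == k) count <- count + 1L
    }
    count
}

# Number of orbits of N x M matrices over a 4-letter alphabet under the
# row-permutation x column-permutation action, restricted to matrices with
# pairwise-distinct rows. Explicit orbit-minimum computation over all
# 4^(N*M) matrices, vectorized on base-4 encodings; independent of the
# package's canonicalization.
oracleOrbitCount <- function(N, M) {
    stopifnot(N * M <= 9)
    total <- 4^(N * M)
    codes <- 0:(total - 1)
    # digits in row-major order: cell (i, j) at position (i-1)*M + j
    digits <- matrix(0L, total, N * M)
    for (pos in seq_len(N * M)) {
        pw <- 4^(N * M - pos)
        digits[, pos] <- (codes %/% pw) %% 4L
    }
    distinctRows <- rep(TRUE, total)
    for (i1 in seq_len(N - 1)) for (i2 in (i1 + 1):N) {
        same <- rep(TRUE, total)
        for (j in seq_len(M)) {
            same <- same & (digits[, (i1 - 1) * M + j] ==
                            digits[, (i2 - 1) * M + j])
        }
        distinctRows <- distinctRows & !same
    }
    w <- 4^(N * M - seq_len(N * M))
    orbitMin <- codes
    for (rp in oraclePermList(N)) for (cp in oraclePermList(M)) {
        perm <- integer(N * M)
        for (i in seq_len(N)) for (j in seq_len(M)) {
            perm[(i - 1) * M + j] <- (rp[i] - 1) * M + cp[j]
        }
        permuted <- as.vector(digits[, perm, drop = FALSE] %*% w)
        orbitMin <- pmin(orbitMin, permuted)
    }
    length(unique(orbitMin[distinctRows]))
}

# literal inclusion-exclusion expansion of the per-strain kill probability
# from the per-antibiotic probabilities (alternating sum over subsets)
oracleInclusionExclusion <- function(pj) {
    M <- length(pj)
    total <- 0
    for (size in seq_len(M)) {
        for (subset in utils::combn(M, size, simplify = FALSE)) {
            total <- total + (-1)^(size - 1) * prod(pj[subset])
        }
    }
    total
}

# per-antibiotic kill probabilities evaluated symbolically from the model
# definition (independent of the package's vectorized path)
oraclePerAntibioticKill <- function(phenotypes, X, KP, KD) {
    N <- nrow(phenotypes); M <- ncol(phenotypes)
    out <- matrix(0, N, M)
    for (i in seq_len(N)) for (j in seq_len(M)) {
        if (phenotypes[i, j] == "S") {
            PX <- sum((phenotypes[, j] == "P") * X)
            DX <- sum((phenotypes[, j] == "D") * X)
            out[i, j] <- exp(-KD * DX) * (1 - exp(-KP * PX))
        }
    }
    out
}

# identical-cost helper for sweep-style tests
identicalCosts <- function(params, M) {
    list(crJ = rep(params@cr, M), cdJ = rep(params@cd, M),
         cpJ = rep(params@cp, M))
}

randomCommunity <- function(N, M) {
    Community(matrix(sample(c("P", "S", "D", "R"), N * M, replace = TRUE),
                     N, M))
}
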