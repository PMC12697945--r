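#include <Rcpp.h>
using namespace Rcpp;

// One generation of the lattice birth-death process.
//
// Sites are visited in the supplied order (a fresh random permutation each
// generation). An occupant present at the start of the generation first
// faces death with its precomputed per-site probability (baseline and
// antibiotic risks combined upstream); a survivor attempts birth with its
// strain's birth probability into a uniformly chosen currently-empty
// neighbour. Offspring are flagged and skipped for the rest of the
// generation. All randomness comes from R's RNG, so runs are reproducible
// under set.seed().
//
// occ: L*L strain indices (0 = empty), column-major axial grid (q, r).
// visitOrder: 1-based site visit order.
// deathProb: per-site death probability for the current occupant.
// birthProb: per-strain birth probability.
// [[Rcpp::export]]
IntegerMatrix step_generation_cpp(IntegerMatrix occ, IntegerVector visitOrder,
                                  NumericVector deathProb,
                                  NumericVector birthProb) {
    const int L = occ.nrow();
    IntegerMatrix out(clone(occ));
    LogicalVector newborn(L * L, false);
    // axial hexagonal neighbour offsets (q, r)
    const int dq[6] = {1, -1, 0, 0, 1, -1};
    const int dr[6] = {0, 0, 1, -1, -1, 1};
    RNGScope scope;
    int nbr[6];
    for (int v = 0; v < L * L; ++v) {
        const int site = visitOrder[v] - 1;
        if (newborn[site]) continue;
        const int strain = out[site];
        if (strain == 0) continue;
        if (unif_rand() < deathProb[site]) {
            out[site] = 0;
            continue;
        }
        if (unif_rand() >= birthProb[strain - 1]) continue;
        const int q = site % L;        // row index (column-major matrix)
        const int r = site / L;
        int nEmpty = 0;
        for (int k = 0; k < 6; ++k) {
            int qq = q + dq[k]; if (qq < 0) qq += L; else if (qq >= L) qq -= L;
            int rr = r + dr[k]; if (rr < 0) rr += L; else if (rr >= L) rr -= L;
            const int n = qq + L * rr;
            if (out[n] == 0) nbr[nEmpty++] = n;
        }
        if (nEmpty == 0) continue;
        int pick = (int)(unif_rand() * nEmpty);
        if (pick >= nEmpty) pick = nEmpty - 1;
        out[nbr[pick]] = strain;
        newborn[nbr[pick]] = true;
    }
    return out;
}
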