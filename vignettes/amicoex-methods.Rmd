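---
title: "Coexistence analysis of antibiotic-mediated interaction graphs: models and methods"
author: "AMICoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexistence analysis of antibiotic-mediated interaction graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Microbial strains antagonize each other through secreted antibiotics, and
yet diverse communities persist. AMICoex asks, exhaustively: given N
distinct strains that can interact through M antibiotics, which interaction
graphs admit a stable state in which all strains coexist? A strain's
relation to each antibiotic is one of four discrete phenotypes — producer
(`P`), sensitive (`S`), degrader (`D`) or intrinsically resistant (`R`) —
so an interaction graph is an N x M phenotype matrix, written
`[PD,SP,DS]`-style with one row per strain. The producer-sensitive-degrader
(PSD) motif, in which a degrader attenuates a producer-sensitive
interaction, is the central higher-order structure: degraders protect not
just themselves but every sensitive cell in their neighbourhood.

## The well-mixed model

Relative abundances $X_i$ on the $(N-1)$-simplex evolve by a discrete
replicator map,

$$X_i(t+1) = \frac{f_i(t)\,X_i(t)}{\sum_k f_k(t)\,X_k(t)},
\qquad f_i = r_i\,(1 - p_i^{kill}),$$

with growth rates reduced additively by phenotype costs,

$$r_i = g - c_p \sum_j P_{ij} - c_d \sum_j D_{ij} - c_r \sum_j R_{ij}.$$

The kill probability treats producers and degraders as projecting effective
zones of action whose positions follow a spatial Poisson picture: for
antibiotic $j$,

$$p_{ij}^{kill} = S_{ij}\; e^{-K_D \sum_k D_{kj} X_k}
 \left(1 - e^{-K_P \sum_k P_{kj} X_k}\right),$$

i.e. a sensitive cell dies if it falls inside at least one production zone
and outside all degradation zones. $K_P$ and $K_D$ are the effective
killing and degradation areas ("strengths"). Deaths by different
antibiotics are independent events, so the per-strain kill probability is
combined as $p_i^{kill} = 1 - \prod_j (1 - p_{ij}^{kill})$; this product
form is algebraically identical to the inclusion-exclusion expansion of the
union of events, numerically stabler, and $O(M)$ instead of $O(2^M)$. The
literal alternating-sum expansion is kept in the test suite as an oracle.

Assumptions worth keeping in mind: only relative abundances are tracked
(two strains producing antibiotics against each other can drive each other
to low absolute density without the map noticing); generations are discrete
and non-overlapping; chemical kinetics are implicit in the zone picture.

### Parameters

* `g = 1` — base growth rate per generation (all strains).
* `cr = 0.16` — cost of intrinsic resistance per antibiotic carried,
  in growth-rate units. Production and degradation cost more:
  the *low-cost* combination has `cd = 1.4 cr`, `cp = 2.5 cr`; the
  *high-cost* combination `cd = 2.2083 cr`, `cp = 2.7624 cr`.
* `KP = 40`, `KD = 10` — antibiotic and degrader strengths, dimensionless
  exponents per unit covered-area fraction.
* `jitterScale = 0.0005` — half-width of the per-antibiotic cost
  perturbation (below).

### Cost jitter

Exhaustive surveys perturb the realized cost of each phenotype for each
antibiotic by an independent $0.0005\,U(-1,1)$ draw. The purpose is to
remove knife-edge degeneracies that exist only at exactly identical costs:
for example the mirror strains `(P,D)` and `(D,P)` have exactly equal total
costs under any shared or ratio-scaled perturbation, which leaves a neutral
(spectral radius exactly 1) direction in the dynamics; independent
per-phenotype draws are the smallest perturbation that break every such
degeneracy, which is why they are used here rather than scaling one draw
through the cost ratios (ratio scaling would also amplify the perturbation
by cd/cr and cp/cr, enough to flip classifications whose stability margin
is of the same order). When *comparing* communities (parameter sweeps), the
jitter is switched off so that only the interaction graph differs.

A consequence the user should expect: a handful of communities are genuine
knife edges whose interior fixed point sits within ~0.02 of a simplex face
with a stability margin of ~0.015. For those, different jitter draws
(seeds) can add or remove one or two communities from a survey's stable
set; the survey machinery makes this reproducible per seed but cannot make
it go away, because it is a property of the model at these parameters.

## Enumerating interaction graphs

Two communities are the same interaction graph if one maps to the other by
relabelling strains (row permutation) and antibiotics (column
permutation). `canonicalForm()` computes the lexicographically minimal
matrix over both permutation groups with the fixed letter order
P < S < D < R (frozen so canonical strings are reproducible), and
`enumerateCommunities()` generates every equivalence class by constructing
row multisets over the $4^M$ row alphabet, canonicalizing and
deduplicating. Two redundancy rules apply by default: *distinct strains*
(identical rows collapse to one strain) and *distinct antibiotics*
(identical columns collapse to one antibiotic). Under these rules the
catalogue has 6 members for (N,M) = (2,1) and 6864 for (3,3). The rules are
pluggable arguments and are recorded in the catalogue's provenance slot.

The closed-form cycle-index count implemented in `countFormula()`
(Stirling numbers of the first kind, $\frac{1}{N!M!}\sum_{i,j}
s(N,i)s(M,j)4^{ij}$) is reported alongside the catalogue for orientation
only: it is not an integer in general — the exact Burnside count involves
gcds of cycle lengths rather than products of cycle counts — and the test
suite instead validates enumeration against a brute-force orbit oracle
over all $4^{NM}$ matrices.

Cyclicity (the largest set of columns forming a circulant block, each
column the previous one rotated one element downward) is maximized over row
orderings, since communities are defined only up to strain permutation; a
single column is vacuously circulant (cyclicity 1), and rotation direction
does not matter because columns may be reordered. The measure implemented
is strict: the near-circulant community `[PD,SP,RS]` scores 1, even though
replacing its `R` by `D` yields the circulant `[PD,SP,DS]`. Structural
classification of stable communities therefore reports both cyclicity and
PSD/extension structure rather than folding them into one number.

## Fixed points and stability

`findFixedPoints()` solves $F(X) = X$ in the $(N-1)$-dimensional simplex
chart (the last coordinate eliminated), so the direction induced by
normalization cannot pollute the Jacobian. From each of 100 Dirichlet(1)
starts (uniform on the simplex) a damped Newton iteration runs with
closed-form small-matrix solves, clipping-and-renormalization projection
for steps that leave the simplex, and a direct map-iteration fallback.
Newton runs both from the raw starts — which reaches vertices and unstable
interior roots — and from copies relaxed by 150 map iterations, because an
attracting fixed point near a simplex face can have a large dynamical basin
but a tiny Newton basin. Converged solutions keep a sup-norm residual
below 1e-10, are deduplicated at distance 1e-6, and the N single-strain
vertices (always fixed points of a replicator map) are appended explicitly.

Stability is classified by the spectral radius of the chart Jacobian,
computed by central finite differences with step 1e-7: stable iff the
radius is below $1 - 10^{-9}$ (the margin keeps floating-point knife edges
out of the stable class; borderline points read as unstable). Robustness is
$\max(0, 1 - \rho)$ for stable interior points and 0 otherwise, and the
basin-of-attraction fraction counts Dirichlet(1)-started trajectories
whose terminal state lies within 1e-4 (sup-norm) of a stable interior
fixed point. Trajectories iterate to a sup-norm step change below 1e-13
with a cap of $10^5$ steps; a state is interior when every component
exceeds 1e-6. None of these tolerances is externally prescribed; they were
fixed once at conventional magnitudes for double precision and the test
suite asserts the contracts (residual bounds, contraction near stable
points, agreement between classification and long-trajectory behaviour).

Communities containing a strain whose summed costs reach its growth rate
are not viable as parameterized; surveys record them with zero stable
fixed points and a `viable = FALSE` flag rather than failing.

### Survey reproducibility

`surveyTopologies()` gives every community its own RNG substream, derived
by hashing the canonical notation together with the master seed. Adding or
removing communities from a catalogue therefore never shifts the draws of
the others, surveys are independent of execution order, and a record can
be reproduced in isolation from its community string and the master seed.

### What the surveys find

At the survey conditions above, the (3,2) survey finds exactly one stable
topology per cost combination — the circulant two-PSD community
`[PD,SP,DS]` at low cost and the near-circulant `[PD,SP,RS]` at high cost —
and the (N,1) and (4,2) surveys find none, at either combination. The
(3,3) survey finds 14–15 stable communities at low cost and 5–6 at high
cost depending on the jitter draw; the low-cost set classifies as the
circulant three-PSD community, one acirculant three-PSD community, 10–11
extensions of `[PD,SP,DS]` and 2 extensions of `[PD,SP,RS]`. Three of the
high-cost communities are knife-edge cases of the kind discussed above —
one of them is `[PD,SP,RS]` padded with an all-sensitive antibiotic, so it
inherits that community's high-cost stability by construction — and their
interior fixed points sit close to a simplex face, which is also why the
high-cost stable set is not always contained in the low-cost one.

## The spatial model

The lattice simulator tests how spatial structure changes the picture for
the one-antibiotic PSD motif, which never coexists well-mixed (the
sensitive strain always fixes). It is an individual-based model on a
rhombic torus of hexagonal sites in axial coordinates (every site has six
neighbours; distances are Euclidean in the hex embedding).

* **Chemical fields.** Production and degradation are fast relative to cell
  division, so each generation the antibiotic and enzyme fields are
  recomputed from scratch: source maps (secretion `up` per producer, `ud`
  per degrader) convolved with a periodic isotropic Gaussian kernel
  $e^{-r^2/2K}$ truncated at $3\sqrt{K}$, via FFT. The kernel is
  deliberately unnormalized: a larger diffusivity K then widens the reach
  *and* raises total exposure, so K plays the double role of spread and
  susceptibility. K = 0 degenerates to a point source confined to the
  producer's own site.
* **Dose-response.** The enzyme field $e$ attenuates the local antibiotic
  concentration exponentially, $a_{eff} = a\,e^{-e}$, and the
  per-antibiotic kill probability is $q_j = 1 - e^{-a_{eff,j}}$, combined
  across antibiotics as independent risks — the same exponential forms as
  the well-mixed model. Baseline death composes as $1-(1-d)(1-q)$.
* **Scheduling.** Sites are visited in a fresh random order each
  generation; an occupant faces death first, then a survivor gives birth
  with probability $g$ minus its phenotype costs into a uniformly chosen
  empty neighbour; newborns are skipped until the next generation. The
  inner loop is compiled (Rcpp) but draws from R's RNG, so entire runs are
  bit-reproducible from `set.seed()`.

Demographic defaults follow the reference experiment: `g = 0.7`,
`d = 0.3`, `(cr, cd, cp) = (0.05, 0.105, 0.15)`, `up = ud = 10`,
200 x 200 sites at half occupancy, 6000 generations, 15 replicates per
condition. The test suite runs a reduced design — 50 x 50 sites, 1000
generations, 5 replicates, six (KP, KD) points — which resolves the three
qualitative regimes (sensitive-dominant at negligible antibiotic reach,
degrader-dominant at large KP with small KD, and a broad three-strain
coexistence region at intermediate enzyme reach) in a few seconds per run;
boundaries between regimes at the full published scale are not asserted
anywhere, only region occupancy.

What the generator emulates — and does not. The simulator captures local
dispersal, quasi-static chemical neighbourhoods and demographic
stochasticity. It does not model antibiotic persistence between
generations, condition-dependent (quorum-type) secretion, antibiotic
synergy, efflux-type resistance that raises extracellular concentrations,
nutrient limitation, or evolutionary change of phenotypes. Passing tests
therefore say the implemented mechanism produces the regime structure, not
that real communities will.

## Known limitations

* Only stable fixed points are sought; communities that coexist on limit
  cycles or by permanence without a stable point are reported as
  non-coexisting.
* The replicator formulation tracks relative abundances; mutual-inhibition
  scenarios that collapse absolute densities are invisible to it.
* Enumeration is exhaustive and therefore bounded (N, M at most 5, with a
  combination-count guard); nothing asymptotic is provided.
* Knife-edge communities make survey counts seed-sensitive at the +/- 1-2
  level by the nature of the model, as discussed above.
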