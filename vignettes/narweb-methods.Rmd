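---
title: "Methods: how narweb builds and fits network-area relationships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how narweb builds and fits network-area relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The species-area relationship (SAR) — richness growing as `S = c * A^z` —
is the oldest scaling law in ecology, but communities are networks, not
species lists. narweb asks the analogous question for food-web structure:
how do the number of links, generality and vulnerability, trophic-level
proportions and consumers' diet overlap change as the observation window
grows? Each such network-area relationship (NAR) is summarised by the
exponent z of a fitted power function, and the per-region z-exponents are
then related to environmental structure (habitat clustering, climate
variability) across regions.

The empirical design the package implements works from five inputs: a
species-level trophic *metaweb* (all potential consumer-resource links in
a regional pool), gridded presence/absence ranges, per-cell habitat-class
proportions, per-cell climate layers, and a region label per cell. A local
food web at any area is the induced subgraph of the metaweb on the species
whose ranges intersect that area.

## Local webs and their metrics

`induced_web()` keeps exactly the metaweb links with both endpoints in the
co-occurring species set; self-links (cannibalism) are accepted in the
metaweb but dropped from local webs, since none of the metrics below is
defined to count them. `compute_metrics()` reports:

* `S`, `L`, `L/S`;
* mean and SD of generality (prey per consumer) and vulnerability
  (predators per prey), over species having at least one such link;
  sample SD with `n - 1`, a single-member SD reported as 0 and an empty
  base set as missing;
* fractions of basal (no prey), intermediate (prey and predators) and top
  (prey, no predators) species. Isolated species count as basal: in a
  vertebrate-only web, out-of-web resources (plants, invertebrates,
  carrion, fish) are assumed ubiquitous, so a vertebrate with no
  vertebrate prey is at the base regardless of whether it is preyed on.
  This keeps B + I + T = 1 exactly. A `basal = "inherited"` switch instead
  freezes pool-level basal status in local webs;
* consumers' diet overlap, by default the fraction of predatory links
  whose prey has at least two distinct consumers. The phrase "fraction of
  predatory links shared by predators" is ambiguous; a mean pairwise
  Jaccard variant is provided (`method = "jaccard"`) but the shared-link
  reading is the default and the one used by the pipeline;
* modularity only through an explicit plug-in (`modularity_fn`), default
  missing. The bundled `modularity_igraph()` is a generic
  community-detection score, labelled non-equivalent to any particular
  food-web formulation; empirical metawebs of potential interactions are
  near-unmodular anyway, which is why the reference analysis excluded it.

## Spatial aggregation

Areas are nested prefixes of a deterministic *spiral* ordering of a
region's cells (`spiral_order()`): Chebyshev-distance rings around a
start cell, each ring walked clockwise from due north, skipping cells
outside the grid or region. "Spiral" is not a geometric primitive with a
single definition; this realisation was fixed because it is the canonical
square-grid spiral, makes prefixes maximally compact, and on any full
rectangle every prefix is queen-connected (a tested invariant). On
concave or fragmented regions prefixes can be transiently disconnected —
accepted, since real bioregions are non-convex and the alternative
(detouring) would destroy the ring structure. Replicates
(`sample_paths()`, default 100 per region) draw start cells uniformly
with replacement, each replicate on a sub-seed derived from `(seed, k)`
so results do not depend on evaluation order.

`build_curve()` accumulates the species union over the prefix, induces the
web and computes metrics at every area (`thin` can sparsify the area grid
for large regions; the final area — the full region — is always kept, and
its metrics are path-independent by construction, another tested
invariant). Monotonicity of S(A) and L(A) follows from union growth plus
induced-subgraph monotonicity.

## Power-law fitting

`fit_power()` minimises the raw-scale sum of squares of `y - c * A^z`
with a Levenberg-damped Gauss-Newton iteration, started at the log-log
OLS estimate, tolerance 1e-8 on the relative loss change, at most 1000
iterations; non-convergence falls back to the log-log estimate and is
flagged. A custom optimiser is used instead of `nls()` because exact
power-law data (zero residuals) — which the identity and forced-SAR
checks require — make `nls()` error out. The fit is validated against an
exhaustive grid-search oracle on z (agreement within 1e-3). R² is
computed on the raw scale, matching a raw-scale least-squares objective.
Region-level fits pool the (A, y) points of all replicates into one fit;
a per-replicate-average mode exists for sensitivity analysis, since the
reference description ("fitting power functions to the relationships
obtained across the 100 replicates") does not distinguish the two.

## Richness contribution

Three devices isolate the role of richness:

1. `richness_regressions()`: OLS of log(property) on log S (raw scale for
   proportions and overlap). Under uniform subsampling of a fixed
   metaweb, E[L | S] = L_m S(S-1) / (S_m (S_m - 1)), so the log-log slope
   is slightly above 2 (the derivative of log S(S-1) is 1 + S/(S-1)) —
   links accumulate about twice as fast as species.
2. Null model 1, `null_subsampled_curve()`: same S(A) as an observed
   curve but species drawn uniformly from the pool (nested across steps),
   links induced from the metaweb. Matching is to *cumulative* observed
   richness, not to the sum of per-cell counts — cells share species, and
   reproducing S(A) exactly is the point of the null. A non-nested
   re-draw mode exists because nestedness across steps is an open choice.
3. Null model 2, `null_random_curve()`: same S(A) and L(A), links placed
   uniformly over ordered distinct pairs (no self-links or duplicates,
   the same simple-directed-graph convention as the metrics). Species
   sets stay nested as in model 1; the link set is re-drawn each step,
   since no structure is inherited that nesting could preserve. In the
   dense regime (e.g. S = 100, L = 2000) the probability a species has no
   prey is ((S(S-1)-L)/(S(S-1)))^(S-1) ≈ e^-22 per side, so essentially
   all species are intermediate — the tested signature that trophic-level
   proportions are inherited from the metaweb, not generated by space.

`z_ratio_table()` compares null and observed exponents; ratios near 1
mean richness (plus, for model 1, metaweb structure) explains the scaling.

## Environmental predictors

* Bray-Curtis habitat dissimilarity (`bray_curtis_pair()`):
  `1 - 2*sum(min)/(S_i + S_j)` with the abundance-sum convention
  (`S_i` = total cover), matching vegan's `vegdist`, against which it is
  tested; the literal "number of habitats present" reading is available
  as `convention = "richness"`. Region means are exact all-pairs averages
  up to a pair budget, then an unbiased seeded pair sample flagged
  `estimated`.
* Habitat clustering: Moran's I of each habitat's binary presence layer
  (`morans_i_layer()`, exact evaluation of the double-sum formula,
  validated against a literal brute-force oracle), averaged over habitats
  with defined I (constant layers are skipped). Adjacency is binary rook
  by default — "directly adjacent neighbour" — with queen as an option;
  presence defaults to any positive cover, both open choices in the
  source description.
* Climate: per-region mean and sample SD of each layer.

## Commonality analysis and the z-regression

`commonality_analysis()` fits OLS for all 2^p - 1 predictor subsets and
converts subset R² values into commonality coefficients by Möbius
inversion: with h(B) = R²(full) - R²(complement of B) the coefficient of
subset S is `sum over B ⊆ S of (-1)^{|S|-|B|} h(B)`. Two identities are
enforced by tests at 1e-10: the coefficients sum to the full-model R²,
and each unique effect equals the drop-one R² loss. Predictor selection
(`select_predictors()`) ranks unique effects and greedily enforces
pairwise |r| < 0.7; `fit_z_regression()` then reports OLS coefficients
with t statistics on n - k - 1 degrees of freedom. With few regions the
pipeline first prunes the predictor pool (by |correlation| with the
response) so the commonality model stays estimable — only relevant at
desk scale; a continental analysis with ten regions and two retained
predictors does not hit it.

## The synthetic world

The generators state a fixed world; their defaults are not tuned to test
outcomes.

* `gen_metaweb()`: the niche model, chosen because it produces the
  pyramidal, interval, low-modularity structure typical of real
  vertebrate metawebs. The basal fraction (default 0.7, the regime of the
  European tetrapod pool) is forced by giving the lowest-niche species
  feeding range zero, rather than left emergent, so the pool sits in the
  documented 70%-basal regime. The Beta(1, beta) range scale is
  calibrated analytically so expected connectance equals `C_target`
  (default 0.08: dense enough that desk-scale local webs of a few dozen
  species still carry links); consumers occupy the high-niche tail, so
  the calibration uses their mean niche (1 + b)/2.
* `gen_ranges()`: truncated-lognormal range sizes (median 40 cells,
  sigma 1 — heavy-tailed, as real range-size distributions are), grown as
  rook-connected patches by randomised breadth-first accretion; contiguity
  is what makes spiral aggregation produce smooth SARs. Consumers' median
  range is multiplied by `trophic_range_scaling` (default 3): home ranges
  grow with trophic position, and this is what makes basal SARs steeper
  than top SARs in the synthetic world — without it, all levels would
  share one expected SAR shape and the observed level ordering would have
  no mechanism.
* `gen_habitat()`: K competing domains scored by
  `clustering * distance + (1 - clustering) * noise`; one-hot proportions.
  Moran's I rises monotonically with the clustering strength (tested by
  simulation), which is all the downstream analysis needs.
* `gen_climate_field()`: base + per-row gradient + Gaussian noise; the SD
  summaries then have closed forms the tests pin down.
* `gen_bioregions()`: balanced multi-source randomised BFS; every region
  rook-connected, labels partition the grid.

Each generator consumes its own RNG stream derived from the master seed
by fixed offsets, so outputs are pure functions of (parameters, seed) and
independent of call order.

What a green synthetic run does *not* establish: real ranges are not
perfectly contiguous nor independent of each other; real habitat mosaics
are not one-hot; real metawebs have compiler biases no niche model
emulates; and the real analysis's headline numbers (per-bioregion
z-exponents, the 83% variance explained) depend on those continental data
sets and are deliberately out of reach here. The tests establish the
machinery — metrics, aggregation, fitting, nulls, environment statistics
— against oracles and closed forms, plus the qualitative signatures the
mechanism implies (basal-faster-than-top SARs, null-model limits,
clustering-monotone Moran's I).

## Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col) with row-major cell ids — the one
  unambiguous, testable convention.
* Upscaling (fine-to-coarse presence) is a boolean max-pool; non-divisible
  factors pad with absences bottom/right, preserving "present in at least
  one fine cell". The real 300 m -> 10 km factor is non-integral; an
  integral factor is required here and the discrepancy is documented.
* Habitat proportions are renormalised when within 1e-3 of summing to 1,
  otherwise rejected.
* Curve rows with S = 0 carry missing metrics and are skipped by fits;
  all-zero y errors out; constant layers give undefined Moran's I and are
  skipped by the habitat average.
* CSV floats are written with 10 significant digits so repeated writes
  are byte-identical and round-trips are exact to 1e-9 relative.
* In acceptance criterion 5 the subset sizes start at 30 species: with
  ~5 links at S = 10 the Jensen bias of log L distorts the slope of a
  law that is exact in expectation at every size.

## Known limitations

* The spiral's treatment of out-of-region cells (skip, not detour) is one
  of several defensible readings of the source procedure.
* Consumer overlap's published value is definition-dependent; both
  definitions ship, neither is privileged by evidence.
* The modularity plug-in is explicitly non-equivalent to the source's
  formulation, which is unidentifiable from the text.
* The per-replicate vs pooled fitting ambiguity is resolved by defaulting
  to pooled; both are available.
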