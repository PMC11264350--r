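---
title: "Discriminating woody-species assemblages: models, parameters and design choices"
author: "avalanche package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating woody-species assemblages: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the methods it implements:
the measurement model behind the community matrix, the two dissimilarity
indices, the divisive clustering engine, the indicator statistics, the
evaluation suite, and the synthetic inventory generator used to test all
of it.  It also records the numerical choices and the decisions taken
where the design was genuinely open.

## 1. From stems to a community matrix

National forest inventories record stems on **nested concentric
subplots**: a stem is included only if its DBH reaches the threshold of
one of three circles (radius 15 m for DBH ≥ 30 cm, 10 m for ≥ 15 cm,
5 m for ≥ 8 cm; 8 cm is the census threshold, below which nothing is
recorded).  Design-based per-hectare expansion therefore weights each
stem by the inverse of its circle's area, `10000/(π r²)` — the standard
NFI estimator; no edge correction is applied.  `stemBasalArea()` is the
usual dendrometric closed form `π (d/200)²` in m².

A cluster plot enters the sample only if it passes, in a **fixed
order**, the filters of `filterClusters()`: allowed land use, no
slopover subplot (a subplot crossing a forest boundary, which inflates
richness through edge effects), exactly three non-empty subplots, and
no record left above species level (a cophenetic distance cannot be
assigned to "*Deciduous* spp.").  The fixed order makes the single
rejection reason per cluster deterministic, which keeps the rejection
log stable across runs.  Species-level validation is a configurable
regex (infraspecific markers such as "subsp." are *not* rejected — they
are consolidated into the parental binomial by
`consolidateInfraspecific()`, and abundance columns of merged taxa are
summed).  A user-supplied synonym map replaces full nomenclature
harmonization against taxonomic backbones, which is out of scope here:
matching to the phylogeny is exact on consolidated binomials, with
underscores and spaces interchangeable.

The community matrix entry for sample *s* and species *i* is the sum of
`BA · expansion` over the cluster's **living** stems of that species,
divided by 3 — the mean basal area per hectare across the three
equally designed subplots.  Dead stems are excluded; samples left with
no living stem are dropped and reported.

Sample elevation is the **median** of all raster cells contained in or
crossed by the circle of radius 15 m + recorded GPS error around the
southwestern subplot's centre; cell/circle intersection is decided by
the exact distance from circle centre to cell rectangle.  No-data cells
are excluded, and an all-no-data circle is an error rather than a
silent NA.

## 2. The two dissimilarity indices

`brayCurtis()` is computed on the raw mean-BA abundances (the
convention of the standard community-ecology implementation, against
which it is cross-checked in the tests); a relative-frequency variant
is available via `bc_relative`.

`discriminatingAvalanche()` works on within-sample relative frequencies
`p` (switchable via `da_relative`), with `Δᵢ = |pᵢᵃ − pᵢᵇ|`:

`dA(a,b) = ½ Σᵢ Σⱼ Δᵢ dᵢⱼ Δⱼ`, `dᵢᵢ = 0`,

where `d` is the **normalized cophenetic distance matrix**: tip-to-tip
path lengths on the ultrametric phylogeny divided by the observed
maximum, so values fall in (0, 1] with the maximum exactly 1.
Observed-max division is the minimal transform achieving the documented
range; it is scale-invariant (branch-length units cancel) and
idempotent.

### Normalization of dA

The raw index must be mapped to [0, 1].  Writing `Σ Δ ≤ 2` (equality
iff the supports are disjoint) and `dᵢⱼ ≤ 1`,

`½ Σᵢ Σⱼ≠ᵢ Δᵢ Δⱼ dᵢⱼ ≤ ½ [(ΣΔ)² − ΣΔ²] ≤ ½ [4 − 4/n] = 2(1 − 1/n)`,

with `n` the number of species; the bound is attained by two samples
with disjoint supports, each uniform over half the species, at maximal
interspecies distance (for `n = 2`, one distinct species each at
`d = 1`, raw dA is exactly 1 = 2(1 − 1/2)).  The default
(`mode = "theoretical"`) therefore divides by `2(1 − 1/n)`; a
normalized value of 1 means two samples are completely different both
compositionally *and* phylogenetically, and values can sit strictly
inside (0, 1) even under complete species turnover — the behaviour that
motivates the index.  A frequently quoted bound of `1 − 1/n` refers to
a half-scaled variant of the same form; dividing this implementation's
raw values by `1 − 1/n` would push roughly half of all
strong-turnover pairs above 1, so it is not used.  `mode = "observed"`
provides verbatim min–max scaling over the off-diagonal entries
instead, which forces the extremes to 0 and 1 exactly; it is retained
for exactness checks, not as the default, because pinning the extremes
to the observed sample makes values incomparable across datasets.
Entries are defensively clipped to [0, 1] with a count kept on the
object (`nClipped`); under the theoretical divisor clipping cannot
occur.

`n` in the divisor is the total species count of the community matrix,
not the per-pair union.  Samples with identical composition get
dissimilarity exactly 0 and remain distinct rows.

## 3. The divisive clustering engine

`buildHierarchy()` recursively applies `bestSplit()` to at most
`max_levels = 4` levels — deep enough to expose classes, branches and
assemblages while remaining interpretable.  Each candidate split is the
chain

1. `geodesicDistances()` — symmetric kNN graph on the node's
   dissimilarities; disconnected components are repaired by adding the
   minimum inter-component dissimilarity edge (this keeps geodesics
   finite without distorting local structure); all-pairs shortest
   paths.
2. `isomapEmbed()` — classical scaling of the squared geodesics
   (double-centering + eigendecomposition), top axes with positive
   eigenvalues, scaled by the square root of the eigenvalue.  Requested
   axes beyond the positive spectrum are dropped with a message; a node
   of coincident points degenerates to a single zero axis, which makes
   the downstream split search decline gracefully.  Axis signs follow a
   fixed convention (largest-magnitude loading positive) so embeddings
   are reproducible.
3. `pamCluster()` — partitioning around medoids on the **embedded
   Euclidean** distances (ordination before partitioning).  BUILD
   seeds greedily, SWAP exchanges medoids while the objective
   `Σᵢ d(i, medoid(i))` drops.  Because BUILD+SWAP is a local search,
   small instances (`choose(n, k) ≤ 300` medoid sets) are solved by
   direct enumeration instead, so small clusters are always partitioned
   optimally.  Every tie — seeding, assignment, swap selection — breaks
   to the lowest sample index or first candidate in enumeration order.
4. `splitQuality()` — the partition's score: the sum, over species
   whose best one-sided Fisher p across clusters is below
   `alpha_indicator`, of the species' maximum equalized phi.  The
   search thus prefers splits supported by many faithful indicator
   species, the same criterion used to structure phytosociological
   tables.

The grid searched is `candidate_k_neighbors` (odd values
3..min(30, n−1)) × `candidate_axes` (2..min(10, n−2)) ×
`candidate_children` (2..6), with the first candidate in grid order
kept on ties.  One eigendecomposition per neighbourhood size serves all
axis counts (classical-scaling axes are nested), which keeps the search
tractable.  A node is left terminal when it is too small
(`< 2 · min_cluster_size`, default `min_cluster_size = 3`), at maximum
depth, or when no candidate yields a single significant indicator with
all children at least `min_cluster_size`; the reason is recorded per
node.  These search ranges and thresholds are explicit
operationalizations — the published descriptions of this family of
algorithms do not pin them down, so exact reproduction of any
particular study's cluster counts is an aspiration, not a guarantee.

`cutAssemblages(h, level)` labels each sample by its deepest ancestor
node at or above the level; terminal nodes shallower than the cut keep
their terminal label, so cuts always refine across levels.

## 4. Indicator statistics

Presence is abundance > 0 (the census threshold has already filtered
trace records).  For a species and cluster, `fisherIndicator()` is the
one-sided (enrichment) hypergeometric tail — indicator semantics test
over-representation, not any association.  `equalizedPhi()` computes
the 2×2 phi coefficient after virtually re-weighting every cluster to
equal size `N/k` (fractional weights), then collapsing to in-cluster
vs out-of-cluster; the equalization removes the dependence of phi on
cluster-size imbalance, and a degenerate margin returns 0.  The tests
verify the re-weighting against a literal sample-duplication oracle.

`isotab()` assembles the full synoptic table (frequency %, phi, p per
species × cluster, plus total frequency) sorted by significance then
fidelity, with a "headline" view at the characterization thresholds
p ≤ .001 and total frequency ≥ 50%.  Raw p-values are reported — the
convention of synoptic tables — with a Holm adjustment available but
off by default.

## 5. Evaluation suite

- `mantelTest()`: Spearman correlation of the lower triangles, null by
  simultaneous row/column permutation of the second matrix,
  `p = (1 + #{ρ* ≥ ρ}) / (1 + n_perm)` (never zero).  Because a
  matrix permutation only permutes the triangle's multiset of values,
  ranks are computed once and each permutation costs one Pearson
  correlation on rank vectors — this is what makes 500-replicate null
  calibrations affordable.
- `copheneticCorrelation()`: Pearson correlation between the original
  dissimilarities and dendrogram distances.  A divisive level
  hierarchy carries no metric heights, so the dendrogram distance of
  two samples is `max_levels + 1 − depth(deepest common node)` with
  the root at depth 0.
- `adjustedRand()`: Hubert–Arabie ARI, delegated to the standard
  mclust implementation and verified against exhaustive pair counting
  over all set partitions of six items in the tests.
- `withinSS()`: distance-based WSS, `Σ_c (Σ_{i<j∈c} d²ᵢⱼ)/|c|`, which
  by Huygens' theorem equals the sum of squared distances to centroids
  whenever `d` is Euclidean — verified numerically.
- `clusterDistanceStats()`: mean dissimilarity over within-cluster
  pairs (per cluster and pooled over pairs) and between-cluster pairs;
  singleton clusters report NA rather than a fabricated value.  Both
  the pooled-pairs mean and the per-cluster means are emitted because
  published summaries are ambiguous between the two averaging schemes.
- `kruskalWallisGroups()`: tie-corrected H with the chi-square
  approximation (standard at these group sizes); all-identical values
  return H = 0, p = 1 instead of NaN.

`evaluateClustering()` bundles all of the above for a BC/dA pair of
matrices and hierarchies; degenerate single-cluster hierarchies yield
NA diagnostics rather than errors so a report is always produced.

## 6. The synthetic inventory generator

`generateSyntheticNFI()` emulates the statistical structure the
analysis assumes, with one global random stream per run:

- **Phylogeny**: a coalescent (hence ultrametric, binary) tree;
  consecutive tips in cladewise order share synthetic genera, so
  genus-level noise labels are phylogenetically plausible.
- **Pools**: each of `n_assemblages` (default 4) gets a focal clade
  found by walking up from a seed species (seeds chosen by greedy
  farthest-point selection on cophenetic distances) until the clade
  reaches ~`n_species/n_assemblages` tips.  Within the clade, weights
  follow a geometric rank-abundance series (ratio 0.65, ranked by
  distance from the seed): every assemblage has dominant, constant
  species and a tail of rarer ones, as real vegetation classes do —
  without dominants, within-assemblage turnover swamps the
  between-assemblage signal and no classifier (nor a field ecologist)
  could delimit the types.  `phylo_signal` mixes this clade
  concentration with a uniform background; at 0 the pools are
  tree-independent, at the default 1 they are pure clades.
- **Landscape**: plots placed uniformly on a rectangle whose elevation
  field rises linearly along one axis (plus a mild transverse ripple),
  spanning 50–2550 m; the written ESRI-ASCII raster has 30 m cells.
  Each assemblage owns a Gaussian elevation niche (sd
  `niche_width = 150` m) centred at evenly spaced elevations, so the
  four default niches are effectively disjoint; a plot's assemblage is
  drawn with probability proportional to the niche densities at its
  elevation.
- **Plots**: per-plot species richness is a rounded normal
  (mean 4.96, sd 2.14, clipped to [1, 12]) and the per-plot basal-area
  target is lognormal (mean 30.4 m²/ha, CV 0.42) — the summary
  statistics a Caucasus-scale NFI reports.  Species are drawn from the
  pool weights; their BA shares follow the weights with gamma noise;
  stems with truncated-lognormal DBH (≥ 8 cm) are added on random
  subplots until each species reaches its share.
- **Noise**: 5% each (configurable) of dead stems, slopover subplots
  and genus-only labels exercise every filter; the retained fraction
  of clusters then mimics the accounting of a real sample definition.

What the generator does **not** emulate: spatial autocorrelation of
forest structure, the real sampling-grid geometry, GPS error beyond a
constant, competition or size–density relationships within plots, and
imbalanced or nested assemblage overlap.  Passing parameter-recovery
tests therefore show that the pipeline recovers *clean, elevation-zoned
clade-structured assemblages*; they do not certify performance on
gradual ecotones or heavily intermixed communities.

## 7. Problem sizes and reproducibility

The shipped tests run the full pipeline at 100–200 cluster plots with
60–90 species, and the acceptance script at 300 plots — sizes chosen so
a complete two-hierarchy analysis stays in the tens of seconds on one
core while leaving every code path (filters, bridging, degenerate
embeddings, terminal rules) exercised; the method itself has been run
at the ~1000-plot default (`syntheticConfig()$n_clusters`) in the same
way, only slower.  All randomness flows from explicit seeds; searches,
embeddings and PAM are tie-broken deterministically, so identical
configurations reproduce bit-identical reports.

## 8. Known limitations

- The dissimilarity matrices are dense: memory and the O(n²·S²) dA
  cost grow quadratically in plots; beyond ~5000 plots a blocked or
  sparse implementation would be needed.
- The dendrogram distance used for cophenetic correlation is ordinal
  (level depths), which bounds the attainable correlation below 1 even
  for a perfect hierarchy on metric data.
- Fisher's test treats plots as exchangeable; spatial pseudoreplication
  in a real systematic grid is not corrected.
- The headline indicator thresholds (p ≤ .001, total frequency ≥ 50%)
  are reporting conventions, not inferential guarantees, and with many
  small clusters the total-frequency filter can legitimately leave the
  headline view empty.
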