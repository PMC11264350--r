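# avalanche

Discrimination of woody-species assemblages from National Forest
Inventory (NFI) data, comparing a species-neutral dissimilarity
(Bray–Curtis) with one that weights compositional differences by
interspecies phylogenetic distance (the Discriminating Avalanche index).

## Who this is for

Forest ecologists and inventory analysts who have (a) stem-level records
from nested concentric sample plots (species, DBH, subplot, status),
(b) an ultrametric phylogeny covering the species list, and optionally
(c) an elevation raster — and who want an unsupervised, reproducible
classification of the plots into species assemblages, together with
indicator-species tables and quantitative cluster diagnostics.  A
synthetic-inventory generator with known ground truth makes the entire
pipeline testable without any field data.

## The statistics at the core

Plot abundances are **mean basal area** per species and cluster plot
(m²/ha): every living stem of DBH `d` (cm) contributes
`π (d/200)² · 10000/(π r²) / 3`, where `r` is the radius of the
concentric circle its DBH qualifies for (15 m for DBH ≥ 30, 10 m for
≥ 15, 5 m for ≥ 8 cm) and 3 is the number of subplots.

For two plots with abundance vectors `a`, `b`:

- **Bray–Curtis**: `BC = Σᵢ |aᵢ − bᵢ| / Σᵢ (aᵢ + bᵢ)` — all species
  count as equally distinct.
- **Discriminating Avalanche**: with relative frequencies `p`,
  `Δᵢ = |pᵢᵃ − pᵢᵇ|` and normalized cophenetic distances `dᵢⱼ ∈ (0,1]`
  from the phylogeny,

  `dA = ½ Σᵢ Σⱼ Δᵢ dᵢⱼ Δⱼ`,

  normalized by its attainable maximum `2(1 − 1/n)` (`n` species) so
  that 1 means complete turnover between maximally distant species.
  Complete turnover among *close relatives* stays far below 1 — the
  phylogenetic signal the index exists for.

Plots are classified by a divisive isopam-style search: geodesic
distances on a k-nearest-neighbour graph → classical-scaling (isomap)
ordination → partitioning around medoids, with every candidate split
scored by the number and fidelity (equalized phi, one-sided Fisher's
exact test) of its indicator species, recursively to at most four
levels.  Hierarchies are evaluated with Mantel correlation, cophenetic
correlation, adjusted Rand index, distance-based within-cluster sum of
squares, within/between distances, and Kruskal–Wallis tests on sample
elevation.

## Worked example

```r
library(avalanche)

cfg <- syntheticConfig(n_species = 60, n_clusters = 150, seed = 42)
res <- runPipeline(synthetic = cfg, n_perm = 999, seed = 42)

res$community
#> CommunityMatrix: 141 samples x 50 species (mean BA, m²/ha)
#>   total BA per sample: mean 30.98  richness: mean 4.88
#>   sampleData: elevation_m

res$h_da
#> AssemblageHierarchy: 141 samples, 4 levels
#>   clusters per level: 4 / 7 / 12 / 12
#>   terminal assemblages: 12 (stopped: no_indicators, too_small)
```

150 generated cluster plots shrink to 141 samples after the filters
(slopover subplots, genus-only labels, incomplete clusters) — the same
accounting an NFI sample definition applies.  The evaluation report
compares the two classifications:

```
Mantel rho = 0.582 (p = 0.0010)
mean pairwise dissimilarity: BC 0.895 | dA 0.364
terminal assemblages:        BC 24 | dA 12
WSS:                         BC 11.31 | dA 0.1090
mean within-cluster dist:    BC 0.398 | dA 0.0248
ARI between hierarchies = 0.258
Kruskal-Wallis on elevation (dA): H = 126.3, p = 9.96e-22
ARI of dA level I vs generating assemblages = 0.980
```

The two dissimilarity matrices correlate strongly but are far from
redundant; the phylogenetically weighted classification is more compact
(lower WSS and within-cluster distances), uses fewer assemblages, and
its level-I classes recover the four generating assemblages almost
perfectly while separating cleanly along the elevation gradient.
Indicator tables name the species behind each class:

```r
head(indicatorTable(isotab(res$h_da, 1, res$community)), 6)
#>              species cluster freq   phi        p total_freq
#> 1 Genus08 species022       2 95.6 0.970 2.97e-34       30.5
#> 2 Genus01 species001       1 97.4 0.983 1.06e-33       27.0
#> 3 Genus08 species023       2 80.0 0.866 1.88e-25       25.5
#> 4 Genus17 species047       4 81.8 0.878 1.62e-23       19.1
#> 5 Genus01 species003       1 76.9 0.845 5.22e-23       21.3
#> 6 Genus08 species024       2 73.3 0.821 1.74e-22       23.4
```

Each class is anchored by a dominant, faithful species (phi near 1) —
the structure a field ecologist would use to label the assemblage.

To run on real data instead, pass files:

```r
res <- runPipeline(stems = "stems.csv", tree = "phylogeny.nwk",
                   raster = "elevation.asc", out_dir = "out/")
```

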