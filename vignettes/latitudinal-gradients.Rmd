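---
title: "Latitudinal gradients in richness and assemblage root distance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latitudinal gradients in richness and assemblage root distance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latgrad)
```

## The analysis

`latgrad` implements a macroecological pipeline for asking whether the
latitudinal gradient in species richness is accompanied by a gradient in the
evolutionary *derivedness* of local assemblages. Derivedness is measured by
the **root distance** (RD) of each species — the number of nodes separating
its tip from the root of a phylogeny — and assemblages are scored by the
**mean root distance** (MRD) of the species co-occurring in a grid cell. RD
is purely topological: it needs no branch lengths and no calibrated ages,
which is what makes it usable with supertrees. Its absolute value depends on
a counting convention, but (as shown below) no downstream statistic does.

The pipeline stages are:

1. **Gridding** (`build_grid()`, `rasterize()`): species range polygons are
   rasterized onto a lattice of 100 × 100 km squares in an equal-area
   projection; each cell records which species' ranges overlap it.
2. **Cell metrics** (`root_distances()`, `cell_metrics()`): per-cell
   richness, MRD over the species with an RD, and the richness of the
   *basal* and *derived* quartile subsets of species.
3. **Latitude smooths** (`fit_smooth()`): penalized-spline models of
   richness and MRD against cell latitude, summarized by deviance explained
   and an approximate smooth-term test.
4. **Spatial diagnostics** (`correlogram()`): Moran's *I* of the model
   residuals at 10 distance classes, each with a Monte-Carlo permutation
   p-value (200 permutations), to check whether spatial autocorrelation
   threatens the smooth-term significance.
5. **Total vs basal/derived comparison** (`pearson_r()`,
   `compare_correlograms()`): per-cell Pearson correlations of total
   against basal and derived richness, and model-II (reduced major axis)
   regression between their Moran's *I* correlograms, with one-delete
   jackknife standard errors over distance classes.

`latgrad_run()` chains all stages from one seeded configuration and returns
a classed object with `print`, `summary` and `plot` methods.

## Root distances and the quartile split

RD counts the internal nodes on the root-to-tip path, **counting the root
and excluding the tip**: both tips of `(A,B);` have RD 1. The phrase
"number of nodes separating the species from the base" leaves the root's
inclusion open; any fixed offset `c` shifts every cell's MRD by exactly `c`
(linearity of the mean), so correlations with latitude, smooth shapes and
quartile memberships are all unchanged. The convention is therefore a
documentation matter, and it is pinned by tests (including exact shift
equivariance).

Species are ranked from most basal to most derived and the **basal** set is
everything at or below the 25th percentile of RD, the **derived** set
everything at or above the 75th. Because RDs are small integers with heavy
ties, the quantile estimator matters: we use linear interpolation on the
sorted sample (index `h = p(n−1)`, `stats::quantile()` type 7) and include
ties on both sides, so each set holds at least a quarter of the species and
degenerates to *all* species when every RD is equal.

Species present in the range data but absent from the tree are dropped from
all RD-based statistics and reported (never guessed): name matching
normalizes case and space/underscore differences only, since silent fuzzy
matches are worse than an explicit drop report.

## The grid and the occupancy rule

Square tiling requires a projection in which equal areas are equal squares,
so the analysis grid lives in a cylindrical equal-area projection on the
authalic sphere (R = 6371.0088 km), standard parallel 30°, central meridian
at the bounding-box centre (both configurable). The map factor
`dx dy = R² cos(lat) dlon dlat` makes every 100 × 100 km cell correspond to
exactly (100 km)² of spherical surface; tests verify < 0.5% deviation cell
by cell. Grid origins are snapped to the projection's own lattice so grids
over nested bounding boxes share cell boundaries.

A species occupies a cell when its projected polygon overlaps the cell
square with **positive area** — the common convention for presence–absence
gridding of range maps; merely touching a boundary does not count, and a
centre-in-polygon alternative is available behind `rule = "centroid"`.
Polygon vertices are projected and edges treated as straight segments in the
projected plane (exact for the lon/lat-aligned rectangles the synthetic
generator emits; an approximation of order cell-size for arbitrary
polygons). Cells with zero richness are kept in the tables, flagged
`occupied = FALSE`, and excluded from every statistical stage. No coastline
mask is applied by default because the synthetic data have no coastline.

## Smooth models of latitude

`fit_smooth()` fits `y ~ s(latitude)` through `mgcv::gam()` with a cubic
B-spline basis and a second-order difference penalty (`bs = "ps"`,
`m = c(2, 2)`), basis dimension `k = 10`, and the smoothing parameter
chosen by generalized cross-validation (or fixed by the caller). The
penalty's null space contains straight lines, so the infinite-penalty limit
is the ordinary least-squares line — a tested invariant, as are invariance
of the fit under affine rescaling of latitude and monotone non-increase of
deviance explained in the penalty.

The family defaults to gaussian with identity link for both richness and
MRD (Poisson-log is available for counts); deviance explained,
`1 − D_model/D_null`, is then the familiar R². The smooth term's
significance uses `mgcv`'s approximate test (F-type for gaussian,
deviance-based for Poisson); under an iid null its rejection rate at
α = 0.05 is verified to sit in [0.03, 0.08] by simulation. Two degenerate
cases are defined explicitly: a constant response has deviance explained 0
and p = 1, and an exactly interpolated response (zero residual scale, where
the F statistic degenerates) has p = 0. The predictor is signed latitude in
degrees, matching how richness–latitude relationships are usually plotted;
`abs(latitude)` can be supplied instead for hemisphere-symmetric analyses.

## Moran's I correlograms

For a distance class with binary symmetric weights `w_ij` (1 iff the pair's
distance falls in the class),

$$I = \frac{n}{S_0} \, \frac{\sum_{i \ne j} w_{ij} z_i z_j}{\sum_i z_i^2},
\qquad z_i = x_i - \bar x ,$$

with `S_0` the number of ordered weighted pairs. Weights are not
row-standardized — the classical distance-class correlogram. Distances are
Euclidean in the equal-area plane, consistent with the grid. Ten classes of
equal width spanning zero to the maximum pairwise distance are the default
(matching evenly spaced correlogram axes); equal-pair-count classes at
distance quantiles are an option. Each class's significance comes from a
Monte-Carlo permutation test: values are shuffled across cells 200 times
and `p = (1 + \#\{|I_{perm}| \ge |I_{obs}|\})/(n_{perm}+1)`, two-sided by
default with the +1 correction guaranteeing `p > 0`; a one-sided variant is
exposed. The implementation is checked against a naive O(n²) double loop to
10⁻¹⁰, against the exact value −1 for a checkerboard at the
nearest-neighbour class, against the permutation-null mean −1/(n−1), and
for type-I error calibration.

Pair storage is quadratic in the cell count, so correlograms cap the number
of cells at `max_cells = 3000` by seeded subsampling (recorded in the
result); at the default study size (~9,000 occupied cells) the cap is
active, and all correlograms entering one comparison share a seed so they
share cells and classes.

## Model-II regression and the jackknife

Both the total and subset correlograms are estimates, so their relationship
is summarized by model-II regression: **reduced major axis** by default
(`slope = sign(r)·sd(y)/sd(x)`, through the centroid), with the **major
axis** (principal eigenvector of the covariance matrix) as the named
alternative — the two are distinct estimators and both are exposed because
the field's terminology conflates them. We regress subset *I* (y) on total
*I* (x), so a slope near 1 with high R² reads "the subset mirrors the
total's spatial structure"; a swap flag reverses the axes (for RMA this
just inverts the slope). Standard errors of slope and R² come from the
one-delete jackknife over the distance classes,
`SE = sqrt(((n−1)/n) Σ (θ_(i) − θ̄)²)`, with degenerate leave-one-out
replicates excluded and counted. Reported "±" values are these jackknife
SEs, not confidence-interval half-widths.

One quantitative caveat, measured with this package's own generator: the
RMA slope between correlograms is deflated by the subset's per-cell
sampling noise, roughly by `pV/(pV + (1−p)E)` for a fraction-`p` subset of
a community whose cell richness has variance-to-mean ratio `V/E`. A
300-species synthetic community has `V/E ≈ 1`, so even a subset sharing the
total's structure by construction regresses with slope well below 1;
empirical continental richness surfaces have `V/E ≫ 1`, which is why
published slopes cluster near 1. Slopes from synthetic runs should be read
with that in mind.

## The synthetic generator

Real range compilations and supertrees are licensed data, so the generator
stands in for them with the statistical features the analysis actually
consumes:

* **Topology** — Yule (pure-birth) trees via `ape::rphylo(birth = 1,
  death = 0)`, tips relabelled `sp1…spN`; internal edges are collapsed
  independently with probability `polytomy_prob` to emulate supertree
  polytomies. Branch lengths are discarded: only topology feeds RD.
* **Ranges** — one axis-aligned rectangle per species (centroid ±
  half-widths), clipped to the bounding box. Rectangles are sufficient to
  induce the gridded richness/MRD structure the analysis consumes and keep
  the geometry exact under the projection. Half-widths are log-normal
  (`meanlog = log 2.5°`, `sdlog = 1`), spanning roughly 0.3° to 20° — range
  sizes across orders of magnitude, as in real compilations.
* **Richness gradient** — centroid latitudes are drawn from a zero-centred
  truncated normal with `sd = halfspan/(1 + richness_gradient)`;
  the default `richness_gradient = 1` concentrates ranges toward the
  equator strongly enough that occupied-cell richness falls off visibly
  toward the box edges. Longitudes are uniform.
* **RD–latitude coupling** — the target correlation
  `rd_latitude_coupling` between RD and |centroid latitude| is imposed by
  rank-matching through a Gaussian copula: RD ranks are mapped to normal
  scores, mixed with independent noise at the target correlation, and the
  drawn latitudes are re-assigned so the ranks of their absolute values
  follow the mixed scores. This controls the correlation directly,
  whatever the RD distribution; over 20 seeds at n = 300 the realized mean
  correlation sits within ±0.1 of the target across the tested range. The
  default, −0.8, plants the structure the pipeline is designed to detect:
  derived species concentrated near the equator.

What the generator does **not** emulate: realistic range shapes,
coastlines, range cohesion along environmental gradients, phylogenetic
autocorrelation of range size or location (each species' range is drawn
independently given its RD rank), extinction, and branch lengths. Passing
tests therefore demonstrate that the machinery recovers planted structure
of the stated form — not that any particular empirical dataset would yield
particular numbers.

A default-scenario run (300 species, bbox −120…−35° lon, −55…55° lat)
grids to a 82 × 122 lattice of which roughly 9,000 cells are occupied; one
end-to-end run, correlograms included, takes a few minutes on one CPU.

## Reproducibility and problem sizes

Every stochastic step descends from one master seed: the scenario uses the
seed itself, the tree the same (its own stage), ranges `seed + 1`, and each
correlogram a distinct fixed offset — so two runs of the same config are
byte-identical, including written CSVs (a tested property). The test suite
uses deliberately scaled problem sizes — e.g. 15 × 15 grids with 1,000
replicate datasets for permutation-test calibration, n = 500 with 1,000
replicates for smooth-term calibration, and 10 replicate scenarios per arm
when checking recovery of the planted MRD–latitude coupling. That last
choice is deliberate: the per-run cell-level correlation carries
species-level sampling noise that spatial aggregation does not average
away (sd ≈ 0.19 under the null), so single-run checks would be dominated
by draw luck; the mean over seeded replicates estimates the quantity the
property is actually about.

## Known limitations

* RD is a coarse proxy for evolutionary age; clades with equal node counts
  can differ in age, and unbalanced sampling of the tree biases RD. MRD
  averages some of this out but inherits the rest.
* The straight-edge projection of polygon boundaries is approximate for
  large, non-rectangular polygons; densify such polygons before input if
  sub-cell accuracy at edges matters.
* GeoJSON interior rings (holes) are ignored with a warning; ranges with
  real holes will be slightly over-rasterized.
* The permutation test treats cells as exchangeable under the null; it
  diagnoses autocorrelation but does not correct the smooth-term test for
  it. The intended workflow: inspect the residual correlograms, and only
  refit on spatially thinned data if they show structure.
* Equal-width distance classes can leave far classes with few pairs on
  irregular domains; the pair counts are always reported, and the
  equal-pairs rule is available.
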