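---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`divscape` maps intra-specific plastid genetic diversity and divergence
across a study region by pooling population-level cpDNA haplotype data
from many species, and then asks which climatic, topographic and
anthropogenic variables best account for the diversity pattern. This
vignette records the statistical models, the assumptions behind them, the
defaults, and the design decisions that were genuinely open.

## Population genetic statistics

Chloroplast DNA is effectively haploid and uniparentally inherited, so
each individual carries exactly one haplotype and a population sample is a
vector of haplotype counts over the species' aligned haplotype pool.
Populations with fewer than `min_n = 5` individuals are removed before any
statistic is computed; smaller samples make the frequency-based estimators
unacceptably noisy.

* **Haplotype diversity.** Nei's unbiased estimator
  $H_D = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$, bounded in $[0,1]$,
  equal to 1 exactly when all $n$ sampled individuals differ and 0 exactly
  when the population is monomorphic.
* **Nucleotide diversity.** The per-site version
  $\pi = \frac{n}{n-1}\sum_{i,j} p_i p_j d_{ij}$ where $d_{ij}$ is the
  proportion of differing sites between haplotypes $i$ and $j$ over sites
  at which both carry an unambiguous base. Alignment columns with `-` or
  `N` in either sequence are excluded *pairwise*, and each pair divides by
  its own number of compared sites; pairwise deletion is the common
  default for intergenic-spacer alignments and keeps every informative
  site. Pairs with no comparable sites are excluded with a warning.
* **Pairwise differentiation.** $\Phi_{ST}$ from a two-level analysis of
  molecular variance on squared inter-individual distances. For haplotype
  sequence data the squared distance between two individuals is their
  count of differing nucleotide sites (the default for haplotypic data in
  the standard AMOVA software); a frequency-only variant ($d^2 = 1$ for
  different haplotypes) is available via `method = "frequency"` because
  source studies do not always state which flavor they used. Variance
  components are the usual method-of-moments solutions:
  $\sigma_b^2 = SSD_{within}/(N-2)$,
  $\sigma_a^2 = (SSD_{among} - \sigma_b^2)/n_c$ with
  $n_c = N - (n_1^2+n_2^2)/N$, and
  $\Phi_{ST} = \sigma_a^2/(\sigma_a^2+\sigma_b^2)$. The estimator can be
  slightly negative (within-population diversity exceeding
  between-population differences); negative values are **kept raw** in
  matrices and in Mantel tests, and clamped to zero only when building
  divergence surfaces (configurable), so distance-based analyses see the
  estimator as computed. When both populations are fixed for the same
  haplotype the total variance is zero and the statistic is defined as 0
  with a `degenerate` attribute, keeping downstream matrices finite.
  Note that two populations with *identical polymorphic* compositions
  have zero among-population sum of squares and hence a (slightly)
  negative estimate — the unbiased estimator's expected behavior, not an
  error.

## Genetic landscape surfaces

Surfaces live on a regular lon/lat grid (default resolution 2.5
arc-minutes, about 5 km at the equator) anchored at the north-west corner
of the boundary bounding box and snapped outward to whole cells; a cell
belongs to the landscape when its center falls inside the boundary
polygon (even-odd rule). Interpolation is inverse-distance weighting with
power 2 — the default of the GIS tooling this workflow descends from —
using great-circle distances on a sphere of radius 6371.0088 km and **all**
data points (population counts are small, so no search radius is needed).
IDW output is a weighted mean, hence always bounded by the input value
range, and reproduces a data value exactly when a cell center coincides
with it (coincidence threshold $10^{-9}$ km; exactly co-located input
points are averaged first so weights stay defined).

Diversity surfaces interpolate population $H_D$ values. Divergence
surfaces use the midpoint construction: every population pair contributes
one synthetic point at the arithmetic lon/lat midpoint carrying the
pair's $\Phi_{ST}$. Arithmetic midpoints are valid at regional scale;
regions straddling the antimeridian are not supported. Pair connectivity
defaults to all pairs; a Delaunay-neighbor option (`pair_mode =
"delaunay"`, built by the empty-circumcircle rule in planar lon/lat) is
provided for users who prefer surfaces driven by neighboring pairs only,
since the literature on midpoint landscapes uses both conventions.

Multi-species landscapes are the cellwise arithmetic mean of per-species
surfaces, all clipped to the same boundary first, so every masked-in cell
has full species overlap; a cell is missing only where every input is
missing. Averaging raw (not rescaled) surfaces is the default because the
combined surface should remain on the $H_D$ scale; min–max rescaling per
species is available via `rescale = TRUE` for users who want each species
weighted equally regardless of its diversity range.

Cell areas use the spherical approximation
$(\Delta \cdot \pi/180 \cdot R)^2 \cos\phi$ at the cell-center latitude
$\phi$ — accurate to well under a percent at 2.5-arc-minute cells, and
latitude-dependent, so hotspot areas are true km² sums rather than cell
counts.

## Hotspots and protection

A cell is a hotspot member when its combined diversity exceeds the
landscape mean by more than `z_threshold = 1.5` standard deviations. The
SD is the *population* SD over masked-in cells (dividing by the cell
count): the landscape is the complete population of cells, not a sample.
Members are grouped into connected components with 8-connectivity by
default (diagonal neighbors merge; 4-connectivity by flag) and labeled A,
B, … by descending area. Protection status is decided by cell-center
containment in any protected-area polygon — simpler and deterministic
compared to polygon–cell intersection areas, with quantization error
bounded by one ring of boundary cells — and the headline number is the
area-weighted fraction of hotspot area lying outside all protected areas.
Hotspot polygons are exported to GeoJSON as per-hotspot MultiPolygons of
member-cell rectangles; areas and centroids are computed from the cells
directly, so nothing downstream depends on dissolving the rectangles.

## Isolation by distance

Per species, a Mantel test correlates the upper triangles of the
great-circle distance matrix (km; a planar lon/lat Euclidean option
exists because "geographic distance" is sometimes computed that way in
source studies) and the raw $\Phi_{ST}$ matrix (a Rousset
$d/(1-d)$ linearization is optional). The alternative is one-tailed
("greater"): isolation by distance predicts a positive correlation. The
p-value is $(1 + \#\{r_{perm} \ge r_{obs}\})/(B+1)$ over $B = 999$ joint
row/column permutations of the genetic matrix, seeded and reproducible;
for 7 or fewer populations the full permutation distribution is
enumerated instead and the p-value is exact. Species with fewer than 4
populations, or with degenerate distance vectors, are reported as `NA`
with a note rather than dropped silently.

## Environmental attribution

The response is the combined diversity surface sampled at its own cell
centers; explanatory rasters are sampled at the same centers
(nearest-neighbor when their grids differ), tagged by category
(climatic / topographic / anthropogenic), and rows with any missing value
are dropped and counted.

* **Collinearity filter.** Within each category, while any pair has
  $|r| > 0.7$: take the highest-$|r|$ pair and drop the member with the
  larger mean $|r|$ against all other remaining variables, breaking ties
  toward the lexicographically later name. The drop rule is a
  determinism-motivated choice (the convention in `caret`-style filters);
  the result provably has no within-category pair above the threshold and
  the filter is idempotent.
* **Importance screening.** To balance category sizes, only the two most
  important variables per category enter the final models. Importance is
  random-forest permutation importance (mean increase in MSE when a
  predictor is permuted; 500 trees, 10 permutation repeats, unscaled),
  computed on a seeded subsample of at most 10,000 cells — grid cells are
  heavily spatially autocorrelated, so a subsample loses little
  information and keeps the forest fast. A node-impurity option exists;
  permutation importance is the default because "importance" here means
  the degree to which a predictor reduces residual variance. Categories
  with exactly two variables pass through without fitting.
* **GAMs.** Each selected variable gets a univariate penalized
  thin-plate-spline GAM (`mgcv`, basis dimension 10, capped at the number
  of distinct predictor values) with restricted-likelihood smoothness
  selection (GCV by flag). Reported: adjusted $R^2$, the smooth's
  significance, and the sign of the overall linear drift of the fitted
  curve over the central 90% of the predictor range.
* **Variation partitioning.** With a univariate response, redundancy
  analysis reduces to multiple linear regression, so the partition is
  built from seven OLS fits (C, T, A, CT, CA, TA, CTA), each $R^2$
  Ezekiel-adjusted, $R^2_{adj} = 1 - (1-R^2)(n-1)/(n-p-1)$, and the seven
  unique/shared fractions solved from the inclusion–exclusion linear
  system — so the fractions sum to $R^2_{adj}(CTA)$ exactly (to numerical
  precision) and each is a linear combination of the seven model values.
  Individual fractions can be slightly negative; this is the standard
  adjusted-$R^2$ artifact and is reported untruncated.

Grid cells are *not* independent observations: spatial autocorrelation is
not corrected anywhere in the attribution stage, so p-values there are
optimistic. This mirrors the common practice in diversity-landscape
regressions and is flagged as the package's main inferential caveat.

## The synthetic-study generator

`simulate_study()` generates everything the pipeline consumes, with
ground truth recorded for recovery testing. It emulates:

* a rectangular study region defaulting to the published bounds of the
  Longitudinal Range Gorge Region (95.79–106.12°E, 21.15–30.60°N);
* 15 species (range-configurable), each with 8–30 populations of 5–20
  individuals, drawn from a 12-haplotype pool of 600-bp alignments built
  by 3 random substitutions per haplotype from a random root — numbers
  chosen to resemble published cpDNA phylogeography datasets (hundreds of
  base pairs of intergenic spacer, tens of populations);
* a planted **south-to-north diversity gradient**: per-population
  haplotype frequencies are symmetric Dirichlet draws whose concentration
  rises log-linearly along the gradient,
  $\alpha(s) = \alpha_0 e^{\gamma (s - 1/2)}$ with position $s \in [0,1]$,
  $\alpha_0 = 0.2$ and $\gamma = 4$. The analytic expectation
  $E[1-\sum p_i^2] = (K-1)\alpha/(K\alpha+1)$ is stored as ground truth;
  with these defaults southern populations are frequently monomorphic, as
  in real cpDNA data, and expected diversity spans roughly 0.15–0.9. A
  Dirichlet concentration gradient, rather than a migration simulation,
  directly controls expected $H_D$ and keeps recovery tests near-analytic
  and fast;
* an environmental stack whose noise fields are orthonormalized against
  the coordinate fields and each other, so planted correlations are exact:
  climatic variables load on latitude with weight 0.6 (the known
  climate–topography overlap), `tmp` is constructed to correlate at about
  0.95 with `cld` (guaranteeing the collinearity filter fires), and the
  two anthropogenic fields are exactly uncorrelated noise with no link to
  diversity;
* protected-area rectangles covering a configurable fraction (default
  0.3) of a target cell set, so the expected outside fraction is known up
  to one-cell quantization;
* a "contaminated" mode that adds undersampled populations ($N < 5$) to
  exercise the retention filter.

What the generator does **not** emulate: coalescent or spatially explicit
migration (no isolation-by-distance signal is planted in the haplotype
data; IBD power is tested on constructed distance matrices instead),
realistic climate fields, shared phylogeographic history between species,
and uneven population placement. Passing recovery tests therefore shows
the estimators and the pipeline wiring are correct, not that real data
would yield these effect sizes.

## Numerical and reproducibility choices

* Degenerate inputs are defined, not crashed on: zero total molecular
  variance gives $\Phi_{ST} = 0$ (flagged), a constant surface gives an
  empty hotspot set (flagged), a fully filtered species warns and flags
  rather than erroring.
* All stochastic stages (generator, Mantel permutations, forest
  subsampling and fitting) take explicit seeds, with per-stage sub-seeds
  derived from a single master seed inside 32-bit range; identical
  configurations produce byte-identical output files.
* The pipeline is a plain sequential run that writes every intermediate
  (CSV, ESRI ASCII grids, GeoJSON, JSON manifest); re-running a stage from
  saved intermediates reproduces the end-to-end values. No content-hash
  caching is used — at these problem sizes a full rerun costs about the
  same as validating a cache, and statelessness is easier to trust.
* Rasters are exchanged as ESRI ASCII grids and polygons as GeoJSON —
  plain-text formats with exact round-trips at written precision.
* Test problem sizes: oracle comparisons use populations of $n \le 8$
  individuals (where exhaustive pair enumeration and full AMOVA
  sums-of-squares are feasible), Mantel enumeration uses 5 labels (120
  permutations), null calibration uses 500 Mantel runs and
  2,000-cell partitions, and recovery tests use the full 15-species
  region at 2.5 arc-minutes (about 56,000 masked cells) — chosen so the
  entire suite exercises the full-scale configuration while the
  bulk of iteration happens on sub-second fixtures.

## Known limitations

* cpDNA is a single, maternally inherited, non-recombining locus: the
  landscapes describe plastid diversity, not genome-wide diversity.
* IDW interpolates far beyond the data where populations are sparse;
  combined surfaces inherit that extrapolation. No uncertainty surface is
  produced.
* Cell-center masking and protection tests quantize areas at one-cell
  granularity.
* The attribution stage treats grid cells as exchangeable observations
  (see above); its $R^2$ decomposition is descriptive, not causal.
* Arithmetic pair midpoints and planar Delaunay neighborhoods assume a
  regional (non-antimeridian-crossing) extent.
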