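---
title: "Turnover-based phytogeographical regionalization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turnover-based phytogeographical regionalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoregions)
```

# The problem

Given a large table of georeferenced taxon observations, partition the
landscape into regions such that species composition changes little
within a region and sharply between regions. `phytoregions` does this by
(i) aggregating records onto an equal-area grid, (ii) measuring pairwise
compositional turnover between cells, (iii) clustering cells
agglomeratively, and (iv) reading regions off the dendrogram. Two
companion analyses quantify how a derived classification relates to an
existing regionalization (overlap agreement) and to the environment
(Getis-Ord Gi\* scores per region and variable).

This vignette explains each model, its assumptions, the tunable
parameters, the numerical conventions, and the design decisions that
were genuinely open — the things a maintainer or careful user needs that
the function reference does not spell out.

# Gridding model

**Projection.** Point records in longitude/latitude are projected with
the ellipsoidal Albers equal-area conic (GRS80). The default parameter
set is the standard continental-Australia configuration (central
meridian 132°E, standard parallels 18°S and 36°S, latitude of origin 0):
equal-area projections are the natural choice when cell area must be
constant, and this configuration is the conventional one for
continental-Australia gridding. All parameters are exposed through
`albersParams()`, so any Albers configuration can be substituted. The
forward/inverse pair is implemented from the published formulas; the
inverse iterates on the authalic-latitude relation to below 1e-13 rad,
and a round trip reproduces planar coordinates to well under 1 m.
No projection library is attached: the implementation is self-contained
and cross-checked in the test suite against independently computed
values and geodesic distances.

**Cells.** Cells are squares of `cellSize` meters (default 100 km — a
continental-scale analysis resolution; finer grids shift region
boundaries but mostly preserve major regions). Cell intervals are
half-open, `[lower, upper)`, indices 0-based and row-major: every point
of the plane belongs to exactly one cell, so gridding is deterministic
and reconstruction unambiguous. A record exactly on an interior boundary
belongs to the higher-index cell. Cells with zero records simply do not
appear in the incidence matrix.

**Cleaning.** Records without usable coordinates are always dropped and
logged (`missing_coordinates` / `invalid_coordinates`). Two further
filters are opt-in:

* a land mask (polygon set in geographic coordinates): records outside
  all polygons are dropped (`outside_mask`);
* a spatial-outlier rule (`outlierSd`): a record is dropped when its
  distance to its species' centroid (in projected space) exceeds
  `outlierSd` times the species' *standard distance*
  (root-mean-squared distance to the centroid), the classical spatial
  dispersion measure. Species with fewer than 3 records are never
  flagged. This rule is **off by default**: outlier deletion in
  herbarium workflows is usually a manual, expert step with no single
  published rule, so the package offers an explicit, reproducible
  stand-in rather than silently imitating one.

The rejection log plus the survivors always partition the input exactly
— this is asserted property-style in the tests.

**Name normalization.** Infra-specific taxa are not analysed: names are
truncated at the first rank marker (`subsp.`, `ssp.`, `var.`, `f.`,
`cv.`), case-normalized, and anything with fewer than two tokens (a bare
genus) is rejected. No external taxonomy is consulted; resolving
synonyms against a census is out of scope.

**Redundancy.** Sampling completeness per cell is reported as
`1 - richness / records`. A cell where every record is a new species
scores 0 (a single visit tells you nothing about completeness); repeated
re-recording of the same species pushes the score toward 1. The
conventional "good coverage" threshold of 0.6 is the default reporting
level. The literal phrase "ratio of species records to samples"
sometimes used for this diagnostic is ambiguous; the complement form
used here is the one consistent with a 60% "good level" reading, and is
the established definition of the redundancy index.

# Turnover model

Simpson's beta between the species sets of two cells is

$$\beta_{sim} = \frac{\min(b, c)}{\min(b, c) + a}$$

with $a$ the shared species count and $b, c$ the counts unique to each
cell. Two properties matter for regionalization: richness correction
(adding species unique to the already-richer cell cannot change the
index while the poorer cell attains the minimum) and nestedness
blindness (a flora that is a subset of another scores 0, so a poorly
sampled cell inside a rich region does not spuriously separate). When
$a = 0$ the index is defined as 1. Cells are required non-empty —
empty cells must have been excluded upstream, and the matrix
constructor enforces this.

The full matrix is computed in one sparse cross-product
($A = PP^{\top}$ over the binary incidence $P$), and the $a, b, c$
counts are retained on the object for audit. Identity of the
cross-product route with naive per-pair set arithmetic is asserted over
hundreds of random incidences in the tests.

# Clustering model

**Linkage.** WPGMA (McQuitty): the merged cluster's distance to any
third cluster is the unweighted mean of its two children's distances,
$(d_{ik} + d_{jk})/2$. Merge height equals the merged pair's
dissimilarity (not half of it), so heights live on the same $[0, 1]$
scale as $\beta_{sim}$ and branch lengths (parent height − own height)
are directly interpretable as turnover gaps; reported branch lengths in
the 0.01–0.3 range are typical. WPGMA on a dissimilarity cannot produce
inversions; heights are nonetheless checked and an inversion is a hard
error rather than a silent repair, as a guard on future linkage
extensions.

**Tie-breaking.** Dissimilarity clustering is notoriously sensitive to
the order in which tied merges are taken. Ties (dissimilarities equal
within `tieTol = 1e-12`; a pure floating-point safety margin — the
conceptual tie notion is exact equality) are resolved by Corrected
Weighted Endemism: for each tied candidate pair, the CWE of the **union**
of the two clusters is evaluated, and the highest-CWE pair merges. CWE
of a cell set is

$$\mathrm{CWE} = \frac{1}{|\,\mathrm{taxa}\,|}\sum_{t}\frac{r_t}{R_t}$$

($r_t$ = cells of the set containing taxon $t$, $R_t$ = all cells
containing it), i.e. range-restriction corrected for richness; it is 1
exactly when every taxon of the set occurs nowhere else. Evaluating the
union (rather than each component separately) was an open choice; the
union is what the merge actually creates, so maximizing its endemism is
the direct reading of "merge the most endemic pair", and the component
alternative would in any case need its own secondary rule for combining
two scores. Remaining ties (identical CWE) fall through to lexicographic
order of the unions' sorted member identifiers. The cascade makes the
dendrogram a pure function of the input matrix: tie-saturated inputs
produce byte-identical Newick output across runs, which the tests assert
100 times over.

**Region extraction.** Two criteria define a region: it should be (near-)
contiguous on the grid, and clearly separated from its neighbours in the
tree. Neither fixes a unique cut, so both modes are exposed:

* `k`: cut into exactly *k* clusters (the usual choice when an expected
  region count exists);
* `minBranch`: report all maximal clusters whose subtending branch is at
  least `minBranch` turnover units. No universal numeric value of
  "clearly separated" exists, so this is a user parameter, not a
  constant. Cells in no qualifying cluster stay unlabeled.

Diagnostics report, per region, the subtending branch length and a
contiguity score (largest rook-adjacent connected component / region
size), so both criteria are checkable rather than implicit.

**Serialization.** Dendrograms serialize to Newick with branch lengths;
round trips through a standard parser preserve topology and cophenetic
structure to 1e-9.

# Comparison model

Classifications are compared cell-wise on their common labeled support
(reference schemes may legitimately have gaps between sub-regions;
unlabeled cells are excluded from numerator and denominator). The notion
"a reference sub-region overlaps with one derived region" is ambiguous
when a sub-region straddles a boundary, so two operationalizations are
provided:

* **plurality** (default): each sub-region is matched to the derived
  region covering most of its cells (ties toward the larger derived
  region, then lexicographic); agreement = cells in the matched region.
  This yields a graded $[0, 100]$ statistic.
* **strict**: a sub-region scores its full cell count iff it lies wholly
  inside one derived region, else zero.

Overall agreement is $100 \times \sum \mathrm{agreement} / \sum
\mathrm{size}$. The statistic is invariant to relabeling either
classification, asserted property-style.

Polygon references are rasterized by cell-center containment (even-odd
ray casting with a stable boundary convention; later-listed polygons win
on overlap, with a warning). The polygon container is a minimal
plain-text ring table — this package deliberately avoids a geospatial
stack for what is a point-in-polygon test.

# Environmental model

Variables are aggregated to cell means (arithmetic mean of source values
falling in each cell; missing cells are explicit `NA` and excluded from
all statistics, shrinking the global support $n$ accordingly). Each
(region, variable) pair is scored with the standardized Getis-Ord Gi\*
statistic with binary weights equal to region membership — the focal
"neighborhood" is the whole region, because the question is whether a
*cluster's* values differ from the landscape, not whether a cell's
neighbours do:

$$z = \frac{\sum_{j \in R} x_j - \bar{X} m}{S\sqrt{(nm - m^2)/(n-1)}}$$

with $m = |R|$, $\bar X$ the global mean and $S$ the **population**
standard deviation, per the original 1995 formulation (which
normalization some implementations use is not always documented; the
population form is the seam, isolated in one function, if the sample
form is ever preferred). Significance uses the conventional $|z| > 2$
rule verbatim rather than 1.96, and no multiple-testing correction is
applied by default, matching standard practice for this exploratory
table. Degenerate pairs (zero variance, $m = n$) raise errors in the
single-pair function and are reported as `NA` rows, without aborting the
rest, in the profile function.

Under an exchangeable null the empirical $|z| > 2$ rate over random
fixed-size regions sits near the nominal tail mass (~0.046); the tests
and the acceptance script both recompute this calibration.

# Synthetic-data generator

The generator exists so that every pipeline stage can be verified
against planted ground truth. Defaults are the package's baseline study
conditions and are not tuned per test: a 20 × 25 grid (500 cells of
100 km — the scale of a continental analysis), 5 planted regions, 80
pool species per region, 10% of each pool shared with adjacent regions,
per-cell occupancy 0.8, Poisson(50) records per cell, 5% global-noise
records. Rationale: region pools of ~10² species and ~10¹–10² records
per cell are what continental herbarium datasets deliver per 100-km
cell; 10% sharing and 5% stray records are mild, realistic
contamination levels that leave planted structure recoverable but not
trivially so.

Mechanics: the grid is partitioned into contiguous rectangular blocks
(regions are expected to be near-contiguous; a Voronoi option exists for
robustness work). Each region owns a species pool; a stated fraction of
each pool is also available in adjacent regions. A cell's *community* is
an independent occupancy draw over its region's available pool (a cell
left empty receives one fallback species, so no degenerate cells are
produced). Records per cell are Poisson — the simplest one-parameter
intensity model; each record is a uniform draw from the cell community,
or from the global pool with the noise probability. Coordinates are cell
centers plus uniform jitter in the projected plane, with an option to
inverse-project to longitude/latitude so the full ingest path
(projection included) is exercised end to end. All draws run under
seeds derived deterministically from the scenario seed, so identical
parameters reproduce identical output, and the exact sampled community
(the ground truth) is returned alongside the records.

What the generator does **not** emulate: real floristic composition,
collector bias (roadside clustering, duplicate vouchers), taxonomic
error, or range-shaped (non-block) regions. Passing the planted-recovery
tests therefore demonstrates that the pipeline recovers clean regional
signal through its own machinery — not that any particular real dataset
will yield stable regions.

Under the baseline conditions the full pipeline (grid → turnover →
WPGMA → cut at the planted count) recovers planted labels with ≥95%
mean agreement after optimal label matching across a 20-seed ensemble,
with every recovered region ≥0.9 contiguous; recovery degrades
monotonically as pools blend. Problem sizes used in the validation suite
— ≤12-cell matrices for brute-force oracle identity, ≤50-leaf trees for
linkage-oracle equivalence, 500-cell grids for recovery, 5000 draws for
the Gi\* calibration — were chosen as the smallest sizes at which each
property is sharply testable.

# Numerical conventions and degenerate inputs

* Tie tolerance 1e-12 on dissimilarities (and on CWE scores when
  comparing tied candidates).
* Heights are clamped monotone only within 1e-9 (guarding accumulated
  floating-point drift in the running average); larger inversions error.
* Empty species sets, empty cell sets, zero global variance, and regions
  spanning the whole support are errors, not NaNs — every degenerate
  case is named.
* Half-open intervals everywhere (cells, polygon boundary convention),
  so no point or cell-center is ever double-assigned.
* Duplicate records (same species, same cell) count toward record totals
  (hence redundancy) but collapse to a single presence: the analysis is
  incidence-based throughout.

# Known limitations

* The overlap statistic's plurality matching is one reading of
  "overlapped with only one region"; the strict mode is the other. On
  heavily fragmented references they can differ substantially — report
  which mode you used.
* CWE tie-breaking evaluates the merged union; the per-component
  alternative is not implemented (the seam is a single function).
* The spatial-outlier rule is a reproducible convention, not a
  validated error model; leave it off unless you have inspected its
  rejections.
* WPGMA is the only linkage; the clustering loop is a seam where other
  linkages could be added, but none are exposed.
* No name resolution against external taxonomies; homonyms and synonyms
  pass through normalization unchanged.
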