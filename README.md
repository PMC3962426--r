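# phytoregions

Quantitative bioregionalization from georeferenced species occurrence
records.

Biogeographers partition continents into regions — areas whose biota are
more similar internally than to their surroundings. `phytoregions`
implements a complete, reproducible pipeline for deriving such regions
from raw herbarium-style occurrence data (taxon name + longitude +
latitude), for comparing the result against an existing regionalization,
and for asking which environmental variables make each region distinct.
It is aimed at biodiversity informaticians and biogeographers who have a
large table of point records and want defensible, fully deterministic
regions out the other end.

## The method

1. **Grid.** Records are cleaned (name normalization to binomials,
   coordinate validation, optional land-mask and spatial-outlier
   filters), projected into an Albers equal-area conic plane, and
   aggregated to square grid cells (default 100 km), giving a binary
   site-by-species incidence matrix. Sampling completeness per cell is
   summarized as *redundancy* = 1 − richness / records.

2. **Turnover.** Compositional dissimilarity between every pair of cells
   is Simpson's beta,

   β_sim = min(b, c) / (min(b, c) + a),

   where *a* is the number of species shared by the two cells and *b*,
   *c* the numbers unique to each. β_sim discounts richness differences
   and nestedness: a cell whose flora is a subset of another's scores 0.

3. **Cluster.** Cells are clustered by WPGMA (McQuitty) agglomerative
   linkage on the β_sim matrix. Dissimilarity clustering is prone to
   arbitrary topology when merge candidates tie, so tied merges are
   resolved by a *Corrected Weighted Endemism* (CWE) tie-breaker: among
   tied pairs, the pair whose union has the highest CWE (weighted
   endemism divided by richness) merges first, with a final
   lexicographic rule guaranteeing the same dendrogram on every run.

4. **Extract regions.** Regions are subtrees cut from the dendrogram —
   either exactly *k* clusters or all maximal clusters separated from
   their parent by at least a minimum branch length — with per-region
   diagnostics for branch length and spatial contiguity.

5. **Compare.** A derived classification is scored against a reference
   regionalization on the same grid: each reference sub-region is
   matched to the derived region covering the plurality of its cells,
   and overall agreement is the matched cell percentage.

6. **Environmental correlates.** Each region × variable pair gets a
   Getis-Ord Gi\* z-score measuring whether the region's cell values are
   higher or lower than expected from the continental distribution;
   |z| > 2 is flagged significant (α < 0.05).

A synthetic-data module generates occurrence records, reference
classifications and environmental layers with *planted* regional
structure, so every stage of the pipeline can be validated against known
ground truth.

## Worked example

```r
library(phytoregions)

s <- syntheticScenario(gridRows = 10, gridCols = 12, nRegions = 4, seed = 11)
occ <- generateOccurrences(s, geographic = TRUE)

m <- gridRecords(projectRecords(occ, albersParams()), scenarioGrid(s))
m
#> SiteBySpeciesMatrix: 120 cells x 320 species, 4510 presences, 5974 records

dend <- wpgma(turnoverMatrix(m), m)
cut  <- cutRegions(dend, k = 4)
cut$diagnostics
#>   region size branchLength contiguity
#> 1    R01   30    0.2506345          1
#> 2    R02   30    0.2152485          1
#> 3    R03   30    0.2496045          1
#> 4    R04   30    0.2667871          1

ref <- generateReferenceClassification(s, 0.1)
overlapAgreement(cut$classification, ref)
#> OverlapReport (plurality): 4 reference sub-regions, overall agreement 90.00%

env  <- generateEnvironment(s, offsets = c(6, 2, -2, -6), noiseSd = 0.5,
                            name = "annual_precip")
subset(regionEnvProfile(env, cut$classification), variable == "annual_precip")
#>   region      variable          z significant nCells
#> 1    R01 annual_precip  7.7111891        TRUE     30
#> 2    R02 annual_precip -1.2456020       FALSE     30
#> 3    R03 annual_precip  0.8885085       FALSE     30
#> 4    R04 annual_precip -7.3540956        TRUE     30
```

Four regions of 30 cells each are recovered, every one fully contiguous
(contiguity 1) and well separated (branch lengths 0.22–0.27 in β_sim
units). The reference layout was generated with 10% of cells relabelled,
and the overlap statistic duly reports 90% agreement. The two regions
with the largest planted environmental offsets (+6 and −6) come out as
significant Gi\* hot/cold spots with opposite signs.

The same pipeline runs from the shell in one command:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/phytoregions.R", package="phytoregions"))') \
  pipeline --occurrences occ.csv --reference ref.csv --env env.csv \
  --k 4 --out-dir out/
```

writing `regions.csv`, `dendrogram.nwk`, `turnover_pairs.csv`,
`redundancy.csv`, `overlap.csv` and `gi_star.csv`.

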