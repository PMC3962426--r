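Package: phytoregions
Title: Quantitative Phytogeographical Regionalization from Species Turnover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative bioregionalization from georeferenced
    occurrence records. Records are cleaned, projected onto an Albers
    equal-area conic plane and aggregated to square grid cells; pairwise
    species turnover between cells is measured with Simpson's beta
    dissimilarity; cells are clustered with WPGMA agglomerative linkage using
    a Corrected Weighted Endemism tie-breaker so that tied merges resolve
    deterministically toward more endemic clusters; phytogeographical regions
    are extracted from the dendrogram by cluster count or branch-length
    separation; the resulting classification can be compared with a reference
    regionalization through a cell-overlap agreement statistic; and the
    environmental distinctness of each region is scored with the Getis-Ord
    Gi* hotspot statistic. A synthetic-data module generates occurrence
    records, reference classifications and environmental layers with planted
    regional structure so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    geosphere,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'projection.R'
    'io.R'
    'occurrence-grid.R'
    'turnover.R'
    'clustering.R'
    'comparison.R'
    'env-correlates.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
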