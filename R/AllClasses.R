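#' @import methods
#' @importFrom Matrix Matrix rowSums colSums t crossprod tcrossprod
#' @importClassesFrom Matrix dgCMatrix sparseMatrix
NULL

#' Grid specification for equal-area cell aggregation
#'
#' Describes a square lattice in a projected equal-area plane: cell size in
#' meters, the coordinate of the lower-left corner of cell (0, 0), the number
#' of rows and columns, and the projection parameter set used to move between
#' geographic and planar coordinates. Cells are indexed 0-based, row-major,
#' with half-open intervals \code{[lower, upper)} on both axes, so every
#' point of the plane belongs to exactly one cell and all cells have planar
#' area \code{cellSize^2}.
#'
#' @slot cellSize cell edge length in meters (default 100 km).
#' @slot originX,originY planar coordinates of the grid origin (meters).
#' @slot nRows,nCols grid dimensions.
#' @slot projection named list of Albers equal-area conic parameters, as
#'   produced by [albersParams()].
#'
#' @seealso [gridSpec()], [gridRecords()], [albersParams()]
#' @export
setClass("GridSpec", representation(
  cellSize = "numeric",
  originX = "numeric",
  originY = "numeric",
  nRows = "integer",
  nCols = "integer",
  projection = "list"
))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0) {
    msg <- c(msg, "cellSize must be a single positive number")
  }
  if (object@nRows < 1L || object@nCols < 1L) {
    msg <- c(msg, "nRows and nCols must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param cellSize cell edge length in meters.
#' @param originX,originY planar coordinates of the grid origin.
#' @param nRows,nCols grid dimensions.
#' @param projection Albers parameter list; see [albersParams()]. The default
#'   is the standard continental-Australia Albers configuration.
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(nRows = 10, nCols = 10)
#' @export
gridSpec <- function(cellSize = 100000, originX = 0, originY = 0,
                     nRows, nCols, projection = albersParams()) {
  new("GridSpec", cellSize = as.numeric(cellSize),
      originX = as.numeric(originX), originY = as.numeric(originY),
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      projection = projection)
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%g, %g)\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY))
})

#' Site-by-species incidence matrix
#'
#' Binary presence/absence of species across grid cells, the substrate of all
#' downstream turnover and endemism computation. Rows are retained grid
#' cells (cells with at least one record), columns are species. Raw record
#' counts per cell are kept alongside for the redundancy diagnostic;
#' duplicate records of a species in a cell count toward \code{recordsPerCell}
#' but collapse to a single presence.
#'
#' @slot presence sparse binary cells x species matrix (\code{dgCMatrix}).
#' @slot cells ordered cell identifiers (row-major \code{r###_c###}).
#' @slot species ordered species identifiers.
#' @slot recordsPerCell integer record count per retained cell.
#' @slot cellRow,cellCol 0-based row/column index of each retained cell.
#' @slot grid the [GridSpec-class] the cells live on.
#'
#' @seealso [gridRecords()], [turnoverMatrix()], [redundancy()]
#' @export
setClass("SiteBySpeciesMatrix", representation(
  presence = "dgCMatrix",
  cells = "character",
  species = "character",
  recordsPerCell = "integer",
  cellRow = "integer",
  cellCol = "integer",
  grid = "GridSpec"
))

setValidity("SiteBySpeciesMatrix", function(object) {
  msg <- character()
  p <- object@presence
  if (nrow(p) != length(object@cells) || ncol(p) != length(object@species)) {
    msg <- c(msg, "presence dimensions must match cells x species")
  }
  if (length(p@x) && !all(p@x == 1)) {
    msg <- c(msg, "presence must be strictly binary (0/1)")
  }
  if (nrow(p) > 0 && any(Matrix::rowSums(p) < 1)) {
    msg <- c(msg, "every retained cell must have >= 1 presence")
  }
  if (length(object@recordsPerCell) != nrow(p)) {
    msg <- c(msg, "recordsPerCell must have one entry per cell")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SiteBySpeciesMatrix", function(object) {
  cat(sprintf(
    "SiteBySpeciesMatrix: %d cells x %d species, %d presences, %d records\n",
    length(object@cells), length(object@species),
    length(object@presence@x), sum(object@recordsPerCell)))
})

#' @rdname SiteBySpeciesMatrix-class
#' @param x a \code{SiteBySpeciesMatrix}.
#' @export
cellIds <- function(x) x@cells

#' @rdname SiteBySpeciesMatrix-class
#' @export
speciesIds <- function(x) x@species

#' @rdname SiteBySpeciesMatrix-class
#' @export
presenceMatrix <- function(x) x@presence

#' @rdname SiteBySpeciesMatrix-class
#' @export
recordsPerCell <- function(x) stats::setNames(x@recordsPerCell, x@cells)

#' @rdname SiteBySpeciesMatrix-class
#' @export
richnessPerCell <- function(x) {
  stats::setNames(as.integer(Matrix::rowSums(x@presence)), x@cells)
}

#' Pairwise Simpson's beta turnover matrix
#'
#' Symmetric matrix of Simpson's beta dissimilarities between all grid-cell
#' pairs, with the underlying shared/unique species counts (a, b, c) retained
#' for audit. \code{a[i, j]} is the number of species common to cells i and
#' j, \code{b[i, j]} the number in i but not j, \code{c[i, j]} the number in
#' j but not i.
#'
#' @slot cells ordered cell identifiers.
#' @slot beta symmetric dissimilarity matrix in [0, 1], zero diagonal.
#' @slot a,b,c integer count matrices.
#' @seealso [turnoverMatrix()], [simpsonBeta()], [wpgma()]
#' @export
setClass("TurnoverMatrix", representation(
  cells = "character",
  beta = "matrix",
  a = "matrix",
  b = "matrix",
  c = "matrix"
))

setValidity("TurnoverMatrix", function(object) {
  msg <- character()
  bt <- object@beta
  if (nrow(bt) != length(object@cells) || ncol(bt) != length(object@cells)) {
    msg <- c(msg, "beta must be square over cells")
  } else {
    if (any(abs(bt - t(bt)) > 1e-12)) msg <- c(msg, "beta must be symmetric")
    if (any(diag(bt) != 0)) msg <- c(msg, "beta diagonal must be 0")
    if (any(bt < 0 | bt > 1)) msg <- c(msg, "beta must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TurnoverMatrix", function(object) {
  n <- length(object@cells)
  off <- object@beta[upper.tri(object@beta)]
  cat(sprintf("TurnoverMatrix: %d cells, %d pairs, beta range [%.3f, %.3f]\n",
              n, n * (n - 1L) / 2L,
              if (length(off)) min(off) else NA, if (length(off)) max(off) else NA))
})

#' @rdname TurnoverMatrix-class
#' @param x a \code{TurnoverMatrix}.
#' @export
betaMatrix <- function(x) x@beta

#' WPGMA dendrogram over grid cells
#'
#' A full binary merge tree in \code{hclust}-style encoding: row k of
#' \code{merge} gives the two clusters joined at \code{height[k]} (negative
#' entries are leaves, positive entries earlier merges). Merge heights equal
#' the pair dissimilarity at the time of merging and are non-decreasing
#' (WPGMA on a dissimilarity cannot produce inversions); branch lengths are
#' height differences between a node and its parent.
#'
#' @slot merge integer (n-1) x 2 merge table.
#' @slot height merge dissimilarities, non-decreasing.
#' @slot labels leaf (cell) identifiers.
#' @seealso [wpgma()], [cutRegions()], [toNewick()]
#' @export
setClass("Dendrogram", representation(
  merge = "matrix",
  height = "numeric",
  labels = "character"
))

setValidity("Dendrogram", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (n > 1L) {
    if (nrow(object@merge) != n - 1L) msg <- c(msg, "merge must have n-1 rows")
    if (length(object@height) != n - 1L) msg <- c(msg, "height must have n-1 entries")
    if (is.unsorted(object@height + 1e-12)) {
      msg <- c(msg, "heights must be non-decreasing (no inversions)")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Dendrogram", function(object) {
  cat(sprintf("Dendrogram: %d leaves, root height %.4f\n",
              length(object@labels),
              if (length(object@height)) max(object@height) else 0))
})

#' Coerce a Dendrogram to hclust
#'
#' @param x a [Dendrogram-class].
#' @param ... ignored.
#' @return a \code{stats::hclust} object (usable with [stats::cutree()]).
#' @export
as.hclust.Dendrogram <- function(x, ...) {
  n <- length(x@labels)
  ord <- dendroLeafOrder(x)
  structure(list(merge = x@merge, height = x@height, order = ord,
                 labels = x@labels, method = "wpgma",
                 call = match.call(), dist.method = "simpson_beta"),
            class = "hclust")
}

#' Region classification of grid cells
#'
#' Maps each covered grid cell to one categorical region label. Both the
#' pipeline's own output (a dendrogram cut) and an external reference scheme
#' are represented this way; cells may be unlabeled (\code{NA}) where a
#' reference has gaps.
#'
#' @slot cells cell identifiers.
#' @slot labels region label per cell (\code{NA} = unlabeled).
#' @slot provenance list describing how the classification was produced.
#' @seealso [cutRegions()], [overlapAgreement()], [rasterizeReference()]
#' @export
setClass("RegionClassification", representation(
  cells = "character",
  labels = "character",
  provenance = "list"
))

setValidity("RegionClassification", function(object) {
  msg <- character()
  if (length(object@cells) != length(object@labels)) {
    msg <- c(msg, "one label (possibly NA) per cell required")
  }
  if (anyDuplicated(object@cells)) msg <- c(msg, "cell identifiers must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegionClassification", function(object) {
  lab <- object@labels[!is.na(object@labels)]
  cat(sprintf("RegionClassification: %d cells (%d labeled), %d regions\n",
              length(object@cells), length(lab), length(unique(lab))))
})

#' Construct a RegionClassification
#'
#' @param cells cell identifiers.
#' @param labels region label per cell.
#' @param provenance free-form provenance list.
#' @return a [RegionClassification-class].
#' @export
regionClassification <- function(cells, labels, provenance = list()) {
  new("RegionClassification", cells = as.character(cells),
      labels = as.character(labels), provenance = provenance)
}

#' @rdname RegionClassification-class
#' @param x a \code{RegionClassification}.
#' @export
regionLabels <- function(x) stats::setNames(x@labels, x@cells)

#' @rdname RegionClassification-class
#' @export
nRegions <- function(x) length(unique(x@labels[!is.na(x@labels)]))

#' Corrected Weighted Endemism score of a cell set
#'
#' Weighted endemism (WE) of a set of cells is the sum over taxa present in
#' the set of the fraction of each taxon's total cell range falling inside
#' the set; CWE divides WE by the set's taxon richness, correcting the
#' range-restriction signal for richness. CWE is 1 exactly when every taxon
#' present in the set occurs nowhere outside it.
#'
#' @slot we weighted endemism.
#' @slot richness number of taxa present in the set.
#' @slot cwe \code{we / richness}, in (0, 1].
#' @seealso [cwe()]
#' @export
setClass("CWEScore", representation(
  we = "numeric", richness = "integer", cwe = "numeric"
))

setMethod("show", "CWEScore", function(object) {
  cat(sprintf("CWEScore: WE = %.4f over %d taxa, CWE = %.4f\n",
              object@we, object@richness, object@cwe))
})

#' Spatial overlap report between two classifications
#'
#' Per reference sub-region: the derived region it matches, its cell count
#' on the common support, and the agreement count; plus the overall
#' agreement percentage (100 * summed agreement / summed sub-region cells)
#' and the full confusion matrix.
#'
#' @slot perRegion data.frame with columns reference, matched, size,
#'   agreement.
#' @slot confusion reference x derived cell-count matrix.
#' @slot overallAgreement percentage in [0, 100].
#' @slot mode matching mode used ("plurality" or "strict").
#' @seealso [overlapAgreement()]
#' @export
setClass("OverlapReport", representation(
  perRegion = "data.frame",
  confusion = "matrix",
  overallAgreement = "numeric",
  mode = "character"
))

setValidity("OverlapReport", function(object) {
  msg <- character()
  if (object@overallAgreement < 0 || object@overallAgreement > 100) {
    msg <- c(msg, "overallAgreement must lie in [0, 100]")
  }
  if (any(object@perRegion$agreement > object@perRegion$size)) {
    msg <- c(msg, "per-sub-region agreement cannot exceed its cell count")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "OverlapReport", function(object) {
  cat(sprintf("OverlapReport (%s): %d reference sub-regions, overall agreement %.2f%%\n",
              object@mode, nrow(object@perRegion), object@overallAgreement))
})

#' @rdname OverlapReport-class
#' @param x an \code{OverlapReport}.
#' @export
overallAgreement <- function(x) x@overallAgreement

#' Per-cell sampling redundancy report
#'
#' Redundancy of a cell is 1 - richness / records, a sampling-completeness
#' indicator: 0 when every record is a distinct species, approaching 1 when
#' species are recorded many times over.
#'
#' @slot perCell data.frame with columns cell, records, richness, redundancy.
#' @slot threshold the reporting threshold used.
#' @slot fractionAtThreshold fraction of cells with redundancy >= threshold.
#' @seealso [redundancy()]
#' @export
setClass("RedundancyReport", representation(
  perCell = "data.frame",
  threshold = "numeric",
  fractionAtThreshold = "numeric"
))

setMethod("show", "RedundancyReport", function(object) {
  cat(sprintf("RedundancyReport: %d cells, %.0f%% at redundancy >= %.2f\n",
              nrow(object@perCell), 100 * object@fractionAtThreshold,
              object@threshold))
})

#' Synthetic bioregionalization scenario
#'
#' Parameter set for the synthetic-data generators: a grid partitioned into
#' planted regions (contiguous blocks by default), a species pool per region
#' of which a stated fraction is shared with adjacent regions, a per-cell
#' occupancy probability for pool species, a Poisson sampling intensity for
#' records per cell, and a global-noise record probability. Identical seed
#' and parameters reproduce identical output.
#'
#' @slot gridRows,gridCols grid dimensions.
#' @slot nRegions number of planted regions.
#' @slot regionLayout "blocks" (contiguous rectangles) or "voronoi".
#' @slot poolSizePerRegion species pool size per region.
#' @slot sharedFraction fraction of each pool shared with adjacent regions.
#' @slot occupancyProb probability a pool species occurs in a given cell of
#'   its region.
#' @slot recordsPerCellMean Poisson mean of records per cell.
#' @slot noiseRecordProb probability a record is drawn from the global pool.
#' @slot seed integer seed for the pseudorandom stream.
#' @slot cellSize cell size (m) of the emitted planar coordinates.
#' @seealso [syntheticScenario()], [generateOccurrences()]
#' @export
setClass("SyntheticScenario", representation(
  gridRows = "integer",
  gridCols = "integer",
  nRegions = "integer",
  regionLayout = "character",
  poolSizePerRegion = "integer",
  sharedFraction = "numeric",
  occupancyProb = "numeric",
  recordsPerCellMean = "numeric",
  noiseRecordProb = "numeric",
  seed = "integer",
  cellSize = "numeric"
))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@gridRows < 1L || object@gridCols < 1L) {
    msg <- c(msg, "grid dimensions must be positive")
  }
  if (object@nRegions < 1L ||
      object@nRegions > object@gridRows * object@gridCols) {
    msg <- c(msg, "nRegions must be in [1, nCells]")
  }
  if (!object@regionLayout %in% c("blocks", "voronoi")) {
    msg <- c(msg, "regionLayout must be 'blocks' or 'voronoi'")
  }
  if (object@poolSizePerRegion < 1L) msg <- c(msg, "poolSizePerRegion must be >= 1")
  if (object@sharedFraction < 0 || object@sharedFraction > 1) {
    msg <- c(msg, "sharedFraction must lie in [0, 1]")
  }
  if (object@occupancyProb <= 0 || object@occupancyProb > 1) {
    msg <- c(msg, "occupancyProb must lie in (0, 1]")
  }
  if (object@recordsPerCellMean <= 0) {
    msg <- c(msg, "recordsPerCellMean must be positive")
  }
  if (object@noiseRecordProb < 0 || object@noiseRecordProb >= 1) {
    msg <- c(msg, "noiseRecordProb must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: %d x %d grid, %d %s regions, pool %d (%.0f%% shared), occupancy %.2f, %g records/cell, noise %.2f, seed %d\n",
    object@gridRows, object@gridCols, object@nRegions, object@regionLayout,
    object@poolSizePerRegion, 100 * object@sharedFraction,
    object@occupancyProb, object@recordsPerCellMean,
    object@noiseRecordProb, object@seed))
})

#' Environmental cell-value table
#'
#' Mean value of each environmental variable within each grid cell, in the
#' variable's native units. Missing cells (no source values) are an explicit
#' \code{NA} state and are excluded from all statistics.
#'
#' @slot values cells x variables numeric matrix, rownames = cell ids.
#' @slot grid the [GridSpec-class] the cells live on.
#' @seealso [aggregateEnv()], [giStar()], [regionEnvProfile()]
#' @export
setClass("EnvCellTable", representation(
  values = "matrix",
  grid = "GridSpec"
))

setValidity("EnvCellTable", function(object) {
  msg <- character()
  if (is.null(rownames(object@values)) || is.null(colnames(object@values))) {
    msg <- c(msg, "values must carry cell rownames and variable colnames")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnvCellTable", function(object) {
  cat(sprintf("EnvCellTable: %d cells x %d variables (%d missing values)\n",
              nrow(object@values), ncol(object@values),
              sum(is.na(object@values))))
})

#' @rdname EnvCellTable-class
#' @param x an \code{EnvCellTable}.
#' @export
envValues <- function(x) x@values
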