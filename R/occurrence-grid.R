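# Record cleaning, projection, gridding, and the redundancy diagnostic.

#' Normalize a raw taxon name to a species binomial
#'
#' Infra-specific taxa are not analysed: names are truncated at the first
#' infraspecific rank marker (\code{subsp.}, \code{ssp.}, \code{var.},
#' \code{f.}, with or without the period for the first three), the genus is
#' capitalized and the epithet lower-cased. Names with fewer than two
#' tokens (rank above species) are rejected with \code{NA}.
#'
#' @param rawName character vector of raw names.
#' @return character vector of binomials; \code{NA} where rejected.
#' @examples
#' normalizeName("Acacia dealbata subsp. dealbata")  # "Acacia dealbata"
#' normalizeName("Acacia")                           # NA: rank above species
#' @export
normalizeName <- function(rawName) {
  if (length(rawName) == 0L || any(is.na(rawName)) ||
      any(!nzchar(trimws(rawName)))) {
    stop("empty taxon name")
  }
  markers <- c("subsp.", "subsp", "ssp.", "ssp", "var.", "var", "f.", "cv.")
  vapply(rawName, function(nm) {
    tokens <- strsplit(trimws(nm), "\\s+")[[1]]
    cut <- which(tolower(tokens) %in% markers)
    if (length(cut)) tokens <- tokens[seq_len(cut[1] - 1L)]
    if (length(tokens) < 2L) return(NA_character_)
    genus <- tokens[1]
    epithet <- tolower(tokens[2])
    paste(paste0(toupper(substr(genus, 1, 1)),
                 tolower(substr(genus, 2, nchar(genus)))), epithet)
  }, "", USE.NAMES = FALSE)
}

#' Clean occurrence records
#'
#' Drops records lacking usable coordinates, records outside an optional
#' land mask, and (when \code{outlierSd} is given) spatial outliers farther
#' than \code{outlierSd} standard distances from their species' centroid in
#' projected space (standard distance = root mean squared distance to the
#' centroid; species with fewer than 3 records are never flagged). Every
#' rejection is logged with a reason code, and survivors keep their input
#' order: the log plus the survivors exactly partition the input.
#'
#' @param records data.frame with \code{species} and \code{lon}/\code{lat}
#'   and/or \code{x}/\code{y} columns.
#' @param mask optional \code{phytoPolygons} in geographic coordinates;
#'   records outside all mask polygons are dropped.
#' @param outlierSd optional positive multiplier for the species-centroid
#'   standard-distance rule (requires projected \code{x}/\code{y}).
#' @param projection Albers parameters used to project records on the fly
#'   when the outlier rule needs planar coordinates they lack.
#' @return list with \code{records} (survivors) and \code{rejected}
#'   (data.frame of input row index + reason code).
#' @export
cleanRecords <- function(records, mask = NULL, outlierSd = NULL,
                         projection = albersParams()) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  hasGeo <- all(c("lon", "lat") %in% names(records))
  hasXY <- all(c("x", "y") %in% names(records))
  if (!hasGeo && !hasXY) stop("records carry no coordinate columns")

  if (hasGeo) {
    bad <- is.na(records$lon) | is.na(records$lat)
    oob <- !bad & (abs(records$lon) > 180 | abs(records$lat) > 90)
    reason[bad] <- "missing_coordinates"
    reason[oob] <- "invalid_coordinates"
  } else {
    bad <- is.na(records$x) | is.na(records$y)
    reason[bad] <- "missing_coordinates"
  }

  if (!is.null(mask)) {
    if (!hasGeo) stop("a geographic mask requires lon/lat columns")
    cand <- which(is.na(reason))
    lab <- polygonLabelAt(records$lon[cand], records$lat[cand], mask)
    reason[cand[is.na(lab)]] <- "outside_mask"
  }

  if (!is.null(outlierSd)) {
    if (outlierSd <= 0) stop("outlierSd must be positive")
    cand <- which(is.na(reason))
    if (hasXY) {
      xs <- records$x[cand]; ys <- records$y[cand]
    } else {
      xy <- albersForward(records$lon[cand], records$lat[cand], projection)
      xs <- xy$x; ys <- xy$y
    }
    sp <- records$species[cand]
    for (s in unique(sp)) {
      i <- which(sp == s)
      if (length(i) < 3L) next
      cx <- mean(xs[i]); cy <- mean(ys[i])
      d <- sqrt((xs[i] - cx)^2 + (ys[i] - cy)^2)
      sd0 <- sqrt(mean(d^2))
      if (sd0 == 0) next
      reason[cand[i[d > outlierSd * sd0]]] <- "spatial_outlier"
    }
  }

  keep <- is.na(reason)
  list(records = records[keep, , drop = FALSE],
       rejected = data.frame(row = which(!keep), reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Project records to the equal-area plane
#'
#' Fills planar \code{x}, \code{y} columns by forward Albers projection of
#' \code{lon}/\code{lat} under the grid's projection parameters.
#'
#' @param records data.frame with \code{lon}, \code{lat}.
#' @param grid a [GridSpec-class] (its \code{projection} is used), or an
#'   Albers parameter list.
#' @return records with \code{x}, \code{y} columns filled.
#' @export
projectRecords <- function(records, grid) {
  params <- if (is(grid, "GridSpec")) grid@projection else grid
  if (!all(c("lon", "lat") %in% names(records))) {
    stop("projectRecords needs lon/lat columns")
  }
  bad <- which(is.na(records$lon) | is.na(records$lat) |
               abs(records$lat) > 90 | abs(records$lon) > 180)
  if (length(bad)) {
    stop("unprojectable coordinates at record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  xy <- albersForward(records$lon, records$lat, params)
  records$x <- xy$x
  records$y <- xy$y
  records
}

#' Infer a grid covering projected records
#'
#' Snaps the grid origin down to a multiple of the cell size below the
#' record extent, so cell boundaries are stable across datasets with the
#' same projection.
#'
#' @param records data.frame with planar \code{x}, \code{y}.
#' @param cellSize cell edge length (m).
#' @param projection Albers parameter list.
#' @return a [GridSpec-class] covering all records.
#' @export
inferGrid <- function(records, cellSize = 100000, projection = albersParams()) {
  ox <- floor(min(records$x) / cellSize) * cellSize
  oy <- floor(min(records$y) / cellSize) * cellSize
  gridSpec(cellSize = cellSize, originX = ox, originY = oy,
           nRows = floor((max(records$y) - oy) / cellSize) + 1L,
           nCols = floor((max(records$x) - ox) / cellSize) + 1L,
           projection = projection)
}

#' Aggregate projected records to a site-by-species incidence matrix
#'
#' Each record falls in the half-open cell
#' \code{[origin + i*cellSize, origin + (i+1)*cellSize)} on both axes (a
#' record exactly on an interior boundary belongs to the higher-index
#' cell). Presence is 1 for every (cell, species) with at least one record;
#' duplicate records add to the per-cell record count only. Cells with zero
#' records are excluded.
#'
#' @param records data.frame with \code{species}, \code{x}, \code{y}.
#' @param grid a [GridSpec-class].
#' @return a [SiteBySpeciesMatrix-class].
#' @export
gridRecords <- function(records, grid) {
  stopifnot(all(c("species", "x", "y") %in% names(records)))
  col <- floor((records$x - grid@originX) / grid@cellSize)
  row <- floor((records$y - grid@originY) / grid@cellSize)
  bad <- which(col < 0 | col >= grid@nCols | row < 0 | row >= grid@nRows)
  if (length(bad)) {
    stop("records outside the grid extent at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  id <- cellId(row, col)
  cells <- sort(unique(id))
  species <- sort(unique(records$species))
  i <- match(id, cells)
  j <- match(records$species, species)
  pres <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                               dims = c(length(cells), length(species)),
                               dimnames = list(cells, species))
  pres@x[] <- 1  # collapse duplicates to binary presence
  rc <- cellRowCol(cells)
  new("SiteBySpeciesMatrix",
      presence = as(pres, "CsparseMatrix"),
      cells = cells, species = species,
      recordsPerCell = as.integer(tabulate(i, length(cells))),
      cellRow = rc$row, cellCol = rc$col, grid = grid)
}

#' Per-cell sampling redundancy
#'
#' Redundancy of a cell is \code{1 - richness / records}: 0 when every
#' record is a distinct species, rising toward 1 as species are re-recorded.
#' The report includes the fraction of cells at or above the stated
#' threshold (0.6 is the conventional "good coverage" level).
#'
#' @param mat a [SiteBySpeciesMatrix-class].
#' @param threshold reporting threshold in [0, 1].
#' @return a [RedundancyReport-class].
#' @examples
#' # a cell with 10 records of 4 species has redundancy 0.6
#' @export
redundancy <- function(mat, threshold = 0.6) {
  rich <- as.integer(Matrix::rowSums(mat@presence))
  recs <- mat@recordsPerCell
  if (any(recs < rich) || any(rich < 1L)) {
    stop("inconsistent cell counts: records >= richness >= 1 required")
  }
  red <- 1 - rich / recs
  new("RedundancyReport",
      perCell = data.frame(cell = mat@cells, records = recs,
                           richness = rich, redundancy = red,
                           stringsAsFactors = FALSE),
      threshold = threshold,
      fractionAtThreshold = mean(red >= threshold))
}
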