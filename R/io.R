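# Plain-text readers and writers for every format the pipeline exchanges:
# occurrence tables, cell-label tables, polygon ring tables, environmental
# cell-value tables, sparse incidence triplets, turnover matrices.

.sniffSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read and write occurrence record tables
#'
#' Occurrence files are delimited text (comma or tab, sniffed from the
#' header) with one row per record. Default column names are
#' \code{species}, \code{longitude}, \code{latitude}; planar columns
#' \code{x}, \code{y} are picked up when present. Rows that cannot be
#' parsed are skipped with a warning, never fatal.
#'
#' @param path file path.
#' @param speciesCol,lonCol,latCol,xCol,yCol column names to map.
#' @return data.frame with columns \code{species} and whichever of
#'   \code{lon}, \code{lat}, \code{x}, \code{y} the file provides.
#' @export
readOccurrences <- function(path, speciesCol = "species",
                            lonCol = "longitude", latCol = "latitude",
                            xCol = "x", yCol = "y") {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fill = TRUE,
                          quote = "\"", comment.char = "")
  if (!speciesCol %in% names(df)) {
    stop("occurrence file lacks a '", speciesCol, "' column")
  }
  out <- data.frame(species = as.character(df[[speciesCol]]),
                    stringsAsFactors = FALSE)
  numcol <- function(nm) if (nm %in% names(df)) suppressWarnings(as.numeric(df[[nm]])) else NULL
  lon <- numcol(lonCol); lat <- numcol(latCol)
  x <- numcol(xCol); y <- numcol(yCol)
  if (!is.null(lon)) out$lon <- lon
  if (!is.null(lat)) out$lat <- lat
  if (!is.null(x)) out$x <- x
  if (!is.null(y)) out$y <- y
  if (is.null(lon) && is.null(x)) {
    stop("occurrence file provides neither geographic nor planar coordinates")
  }
  out
}

#' @rdname readOccurrences
#' @param records occurrence data.frame (from [generateOccurrences()] or
#'   [readOccurrences()]).
#' @param geographic write \code{longitude}/\code{latitude} columns (TRUE)
#'   or planar \code{x}/\code{y} (FALSE); chosen automatically from the
#'   columns present when \code{NULL}.
#' @export
writeOccurrences <- function(records, path, geographic = NULL) {
  if (is.null(geographic)) geographic <- "lon" %in% names(records)
  if (geographic) {
    out <- data.frame(species = records$species,
                      longitude = records$lon, latitude = records$lat)
  } else {
    out <- data.frame(species = records$species, x = records$x, y = records$y)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write two-column cell-label tables
#'
#' The cell-label table is the interchange form of a
#' [RegionClassification-class]: delimited text with columns \code{cell}
#' and \code{label}.
#'
#' @param path file path.
#' @return [RegionClassification-class].
#' @export
readCellLabels <- function(path) {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("cell", "label") %in% names(df))) {
    stop("cell-label table needs 'cell' and 'label' columns")
  }
  regionClassification(df$cell, df$label, provenance = list(source = path))
}

#' @rdname readCellLabels
#' @param classification a [RegionClassification-class].
#' @export
writeCellLabels <- function(classification, path) {
  utils::write.csv(data.frame(cell = classification@cells,
                              label = classification@labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a polygon ring table
#'
#' Minimal plain-text polygon interchange: a delimited table with columns
#' \code{label}, \code{ring}, \code{x}, \code{y} (or \code{lon}, \code{lat}),
#' vertices in order within each (label, ring). Rings need not be closed
#' explicitly. Returns a list of polygons, each a list with \code{label} and
#' a list of vertex matrices.
#'
#' @param path file path.
#' @return list of polygons (class \code{phytoPolygons}).
#' @export
readPolygons <- function(path) {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  xc <- if ("x" %in% names(df)) "x" else "lon"
  yc <- if ("y" %in% names(df)) "y" else "lat"
  if (!all(c("label", xc, yc) %in% names(df))) {
    stop("polygon table needs columns label, ring, x/lon, y/lat")
  }
  if (!"ring" %in% names(df)) df$ring <- 1L
  polys <- lapply(split(df, df$label), function(d) {
    rings <- lapply(split(d, d$ring), function(r) {
      cbind(x = as.numeric(r[[xc]]), y = as.numeric(r[[yc]]))
    })
    list(label = d$label[[1]], rings = unname(rings))
  })
  # preserve file order of first appearance (later-listed polygons win on
  # overlap, so order matters)
  polys <- polys[unique(df$label)]
  structure(unname(polys), class = "phytoPolygons")
}

#' Polygons from a list of vertex matrices
#'
#' Programmatic constructor for the polygon container [readPolygons()]
#' produces, useful for masks built in code.
#'
#' @param ... named vertex matrices (two columns x, y), one per polygon.
#' @return \code{phytoPolygons} list.
#' @examples
#' polygonSet(box = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' @export
polygonSet <- function(...) {
  args <- list(...)
  polys <- lapply(names(args), function(nm) {
    list(label = nm, rings = list(unname(as.matrix(args[[nm]]))))
  })
  structure(polys, class = "phytoPolygons")
}

# Even-odd ray-casting point-in-polygon test. Half-open boundary
# convention: the crossing rule counts an edge when one endpoint is
# strictly above the test ordinate and the other is at or below it, which
# assigns boundary points deterministically.
pointInRing <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Point-in-polygon test against a polygon set
#'
#' Returns, for each point, the label of the containing polygon or
#' \code{NA}. With overlapping polygons the later-listed polygon wins and a
#' warning is issued. Multi-ring polygons use the even-odd rule (a second
#' ring acts as a hole).
#'
#' @param px,py point coordinates (same space as the polygon vertices).
#' @param polygons a \code{phytoPolygons} set.
#' @return character vector of labels (NA where uncontained).
#' @export
polygonLabelAt <- function(px, py, polygons) {
  out <- rep(NA_character_, length(px))
  overlap <- FALSE
  for (poly in polygons) {
    inside <- rep(FALSE, length(px))
    for (ring in poly$rings) inside <- xor(inside, pointInRing(px, py, ring))
    if (any(inside & !is.na(out))) overlap <- TRUE
    out[inside] <- poly$label
  }
  if (overlap) warning("overlapping polygons: later-listed label used")
  out
}

#' Write a site-by-species matrix as a sparse triplet table
#'
#' Long-form text with one row per (cell, species) presence plus a records
#' column per cell, reconstructable without loss.
#'
#' @param mat a [SiteBySpeciesMatrix-class].
#' @param path file path.
#' @export
writeMatrixTriplet <- function(mat, path) {
  tri <- Matrix::summary(mat@presence)
  utils::write.csv(data.frame(cell = mat@cells[tri$i],
                              species = mat@species[tri$j]),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(cell = mat@cells, records = mat@recordsPerCell),
                   sub("(\\.[^.]*)?$", "_records\\1", path, perl = TRUE),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a turnover matrix
#'
#' Writes both interchange forms: a square delimited matrix and a long-form
#' pair table with the audit counts (cell_i, cell_j, a, b, c, beta).
#'
#' @param turnover a [TurnoverMatrix-class].
#' @param matrixPath,pairsPath output paths (either may be NULL to skip).
#' @export
writeTurnover <- function(turnover, matrixPath = NULL, pairsPath = NULL) {
  if (!is.null(matrixPath)) {
    m <- turnover@beta
    utils::write.csv(data.frame(cell = turnover@cells, m, check.names = FALSE),
                     matrixPath, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(pairsPath)) {
    n <- length(turnover@cells)
    ut <- which(upper.tri(turnover@beta), arr.ind = TRUE)
    utils::write.csv(data.frame(
      cell_i = turnover@cells[ut[, 1]], cell_j = turnover@cells[ut[, 2]],
      a = turnover@a[ut], b = turnover@b[ut], c = turnover@c[ut],
      beta = turnover@beta[ut]), pairsPath, row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

#' Read an environmental cell-value or point-value table
#'
#' Wide cell tables have a \code{cell} column plus one numeric column per
#' variable; point tables have \code{x}, \code{y} (or \code{longitude},
#' \code{latitude}) plus variable columns and must be aggregated with
#' [aggregateEnv()].
#'
#' @param path file path.
#' @return data.frame.
#' @export
readEnvTable <- function(path) {
  sep <- .sniffSep(path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' @rdname readEnvTable
#' @param env an [EnvCellTable-class].
#' @export
writeEnvTable <- function(env, path) {
  utils::write.csv(data.frame(cell = rownames(env@values), env@values,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a regions x variables Gi* z-score table
#'
#' One row per region, one column per variable; significant scores
#' (|z| > 2) are starred.
#'
#' @param profile data.frame from [regionEnvProfile()].
#' @param path file path.
#' @export
writeGiTable <- function(profile, path) {
  wide <- stats::reshape(
    profile[, c("region", "variable", "z", "significant")],
    direction = "wide", idvar = "region", timevar = "variable")
  zcols <- grep("^z\\.", names(wide))
  scols <- grep("^significant\\.", names(wide))
  out <- data.frame(region = wide$region, stringsAsFactors = FALSE)
  for (i in seq_along(zcols)) {
    nm <- sub("^z\\.", "", names(wide)[zcols[i]])
    out[[nm]] <- sprintf("%.3f%s", wide[[zcols[i]]],
                         ifelse(wide[[scols[i]]], "*", ""))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
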