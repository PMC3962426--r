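# Environmental cell means and the Getis-Ord Gi* distinctness score of
# each region.

#' Aggregate environmental point values to grid-cell means
#'
#' Input is a point-value table (gridded source layers are just dense point
#' tables): planar \code{x}, \code{y} plus one numeric column per variable,
#' or a ready-made wide cell table with a \code{cell} column. Cell value is
#' the arithmetic mean of all source values whose coordinates fall in the
#' cell (half-open cell intervals); cells with no source values are
#' \code{NA} and are excluded from downstream statistics.
#'
#' @param table data.frame of source values.
#' @param grid a [GridSpec-class].
#' @param vars variable column names; defaults to all numeric columns
#'   besides the coordinates.
#' @return an [EnvCellTable-class] over all grid cells.
#' @export
aggregateEnv <- function(table, grid, vars = NULL) {
  allCells <- cellId(rep(seq_len(grid@nRows) - 1L, each = grid@nCols),
                     rep(seq_len(grid@nCols) - 1L, grid@nRows))
  if ("cell" %in% names(table)) {
    if (is.null(vars)) vars <- setdiff(names(table), "cell")
    bad <- setdiff(table$cell, allCells)
    if (length(bad)) stop("cell table contains cells outside the grid: ",
                          paste(utils::head(bad, 5), collapse = ", "))
    vals <- matrix(NA_real_, length(allCells), length(vars),
                   dimnames = list(allCells, vars))
    vals[table$cell, ] <- as.matrix(table[, vars, drop = FALSE])
    return(new("EnvCellTable", values = vals, grid = grid))
  }
  if (!all(c("x", "y") %in% names(table))) {
    stop("point table needs x/y columns (or a cell column)")
  }
  if (is.null(vars)) {
    vars <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                    c("x", "y"))
  }
  col <- floor((table$x - grid@originX) / grid@cellSize)
  row <- floor((table$y - grid@originY) / grid@cellSize)
  inext <- col >= 0 & col < grid@nCols & row >= 0 & row < grid@nRows
  if (!any(inext)) stop("no source values fall inside the grid extent")
  id <- cellId(row[inext], col[inext])
  vals <- matrix(NA_real_, length(allCells), length(vars),
                 dimnames = list(allCells, vars))
  for (v in vars) {
    m <- tapply(table[[v]][inext], id, mean)
    vals[names(m), v] <- m
  }
  new("EnvCellTable", values = vals, grid = grid)
}

#' Getis-Ord Gi* score of a cell set for one variable
#'
#' The standardized Gi* statistic with binary weights equal to region
#' membership, the focal neighborhood being the whole region: with global
#' support of n non-missing cells, region size m, global mean \eqn{\bar X}
#' and population standard deviation S,
#' \deqn{z = \frac{\sum_{j \in region} x_j - \bar X m}
#'              {S \sqrt{(n m - m^2)/(n - 1)}}.}
#' Scores with |z| > 2 flag regions whose values differ significantly from
#' the global distribution (alpha < 0.05). Missing-value cells are excluded
#' from both the global and the regional sums.
#'
#' @param env an [EnvCellTable-class].
#' @param regionCells character cell identifiers of the region.
#' @param variable variable (column) name.
#' @return one-row data.frame: region (NA; filled by
#'   [regionEnvProfile()]), variable, z, significant, nCells.
#' @examples
#' # values (0, 0, 10, 10) with the two 10-valued cells as the region:
#' # Xbar = 5, S = 5, z = (20 - 10) / (5 * sqrt(4/3)) = 1.7320508
#' @export
giStar <- function(env, regionCells, variable) {
  x <- env@values[, variable]
  ok <- !is.na(x)
  x <- x[ok]
  n <- length(x)
  if (n < 2L) stop("global support must contain at least 2 cells")
  inRegion <- names(x) %in% regionCells
  m <- sum(inRegion)
  if (m == 0L) stop("region has no cells with non-missing values")
  if (m == n) stop("degenerate Gi*: region spans the whole support")
  xbar <- mean(x)
  S <- sqrt(mean(x^2) - xbar^2)   # population standard deviation
  if (S == 0) stop("degenerate Gi*: zero global variance")
  z <- (sum(x[inRegion]) - xbar * m) / (S * sqrt((n * m - m^2) / (n - 1)))
  data.frame(region = NA_character_, variable = variable, z = z,
             significant = abs(z) > 2, nCells = m,
             stringsAsFactors = FALSE)
}

#' Gi* environmental profile of a region classification
#'
#' One Gi* score per (region, variable) pair, mirroring a regions-by-
#' variables hotspot table; degenerate pairs (zero variance, region equal
#' to the whole support) are reported with \code{NA} z and a note rather
#' than aborting the remaining pairs. The attribute \code{mostExtreme}
#' names, per region, the variable with the largest |z|.
#'
#' @param env an [EnvCellTable-class].
#' @param classification a [RegionClassification-class] on the same grid.
#' @return data.frame of Gi* rows with attribute \code{mostExtreme}.
#' @export
regionEnvProfile <- function(env, classification) {
  labs <- regionLabels(classification)
  labs <- labs[!is.na(labs)]
  regions <- sort(unique(labs))
  vars <- colnames(env@values)
  rows <- list()
  for (r in regions) {
    cellsR <- names(labs)[labs == r]
    for (v in vars) {
      res <- tryCatch(giStar(env, cellsR, v), error = function(e) {
        data.frame(region = NA_character_, variable = v, z = NA_real_,
                   significant = NA, nCells = length(cellsR),
                   stringsAsFactors = FALSE)
      })
      res$region <- r
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  extreme <- vapply(regions, function(r) {
    zz <- out[out$region == r, ]
    zz <- zz[!is.na(zz$z), ]
    if (nrow(zz) == 0L) NA_character_ else zz$variable[which.max(abs(zz$z))]
  }, "")
  attr(out, "mostExtreme") <- stats::setNames(extreme, regions)
  out
}
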