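# Spatial agreement between a derived classification and a reference
# regionalization on a common grid.

#' Rasterize a reference regionalization onto the grid
#'
#' Polygon input: each grid cell takes the label of the polygon containing
#' its center (later-listed polygons win on overlap, with a warning; cells
#' whose center lies in no polygon stay unlabeled). Cell-label table input
#' is validated against the grid extent and passed through.
#'
#' @param reference a \code{phytoPolygons} set (vertices in the grid's
#'   planar coordinates, or geographic when \code{geographic = TRUE}) or a
#'   [RegionClassification-class].
#' @param grid a [GridSpec-class].
#' @param geographic polygons are in lon/lat and cell centers must be
#'   inverse-projected before the containment test.
#' @return a [RegionClassification-class] over all grid cells (possibly
#'   with NA labels).
#' @export
rasterizeReference <- function(reference, grid, geographic = FALSE) {
  if (is(reference, "RegionClassification")) {
    rc <- cellRowCol(reference@cells)
    if (any(rc$row >= grid@nRows | rc$col >= grid@nCols)) {
      stop("reference cells fall outside the grid extent")
    }
    return(reference)
  }
  if (!inherits(reference, "phytoPolygons")) {
    stop("reference must be polygons or a RegionClassification")
  }
  ij <- expand.grid(col = seq_len(grid@nCols) - 1L,
                    row = seq_len(grid@nRows) - 1L)
  cx <- grid@originX + (ij$col + 0.5) * grid@cellSize
  cy <- grid@originY + (ij$row + 0.5) * grid@cellSize
  if (geographic) {
    ll <- albersInverse(cx, cy, grid@projection)
    lab <- polygonLabelAt(ll$lon, ll$lat, reference)
  } else {
    lab <- polygonLabelAt(cx, cy, reference)
  }
  if (all(is.na(lab))) {
    stop("no grid cell center falls inside any reference polygon (extent/CRS mismatch?)")
  }
  regionClassification(cellId(ij$row, ij$col), lab,
                       provenance = list(source = "polygons"))
}

#' Spatial overlap agreement between two classifications
#'
#' Comparison is restricted to cells labeled in both classifications. In
#' \code{plurality} mode each reference sub-region is matched to the single
#' derived region covering the plurality of its cells (ties broken toward
#' the larger derived region, then lexicographically) and its agreement
#' count is the number of its cells in that region. In \code{strict} mode a
#' sub-region scores its full cell count if it lies wholly inside one
#' derived region and zero otherwise. Overall agreement is 100 times the
#' summed agreement over the summed sub-region cell counts.
#'
#' @param derived,reference [RegionClassification-class] objects on the
#'   same grid.
#' @param mode "plurality" (default) or "strict".
#' @return an [OverlapReport-class].
#' @examples
#' d <- regionClassification(1:8, rep(c("P", "Q"), each = 4))
#' r <- regionClassification(1:8, c("X", "X", NA, NA, "X", "Y", "Y", "Y"))
#' overallAgreement(overlapAgreement(d, r))  # 83.33
#' @export
overlapAgreement <- function(derived, reference,
                             mode = c("plurality", "strict")) {
  mode <- match.arg(mode)
  dl <- regionLabels(derived)
  rl <- regionLabels(reference)
  common <- intersect(names(dl)[!is.na(dl)], names(rl)[!is.na(rl)])
  if (length(common) == 0L) {
    stop("classifications share no labeled cells")
  }
  dl <- dl[common]; rl <- rl[common]
  conf <- table(reference = rl, derived = dl)
  derivedSizes <- table(dl)

  per <- do.call(rbind, lapply(rownames(conf), function(sub) {
    counts <- conf[sub, ]
    total <- sum(counts)
    if (mode == "plurality") {
      best <- which(counts == max(counts))
      if (length(best) > 1L) {
        sz <- derivedSizes[names(counts)[best]]
        best <- best[sz == max(sz)]
        best <- best[order(names(counts)[best])][1]
      }
      matched <- names(counts)[best]
      agree <- as.integer(counts[best])
    } else {
      inside <- counts > 0
      if (sum(inside) == 1L) {
        matched <- names(counts)[inside]
        agree <- as.integer(total)
      } else {
        matched <- NA_character_
        agree <- 0L
      }
    }
    data.frame(reference = sub, matched = matched, size = as.integer(total),
               agreement = agree, stringsAsFactors = FALSE)
  }))

  new("OverlapReport", perRegion = per,
      confusion = unclass(conf),
      overallAgreement = 100 * sum(per$agreement) / sum(per$size),
      mode = mode)
}
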