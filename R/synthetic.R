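# Synthetic occurrence records, reference classifications and
# environmental layers with planted regional structure, so every pipeline
# stage can be exercised and verified without external data.

#' Construct a synthetic scenario
#'
#' The defaults describe the baseline study conditions used throughout the
#' package's own validation: a 20 x 25 grid of 100 km cells partitioned
#' into 5 contiguous block regions, 80 pool species per region of which
#' 10\% are shared with adjacent regions, 0.8 per-cell occupancy, Poisson
#' sampling at 50 records per cell, and 5\% global-noise records.
#'
#' @param gridRows,gridCols grid dimensions.
#' @param nRegions number of planted regions.
#' @param regionLayout "blocks" (contiguous rectangles) or "voronoi"
#'   (nearest planted seed cell; irregular but near-contiguous).
#' @param poolSizePerRegion species pool size per region.
#' @param sharedFraction fraction of each pool shared with adjacent regions.
#' @param occupancyProb per-cell occupancy probability of pool species.
#' @param recordsPerCellMean Poisson mean of records per cell.
#' @param noiseRecordProb probability a record is drawn from the global
#'   pool regardless of region.
#' @param seed integer seed; identical seed + parameters reproduce
#'   identical output.
#' @param cellSize planar cell size (m) of emitted coordinates.
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(gridRows = 20, gridCols = 25, nRegions = 5,
                              regionLayout = "blocks",
                              poolSizePerRegion = 80, sharedFraction = 0.1,
                              occupancyProb = 0.8, recordsPerCellMean = 50,
                              noiseRecordProb = 0.05, seed = 1,
                              cellSize = 100000) {
  new("SyntheticScenario", gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), nRegions = as.integer(nRegions),
      regionLayout = regionLayout,
      poolSizePerRegion = as.integer(poolSizePerRegion),
      sharedFraction = as.numeric(sharedFraction),
      occupancyProb = as.numeric(occupancyProb),
      recordsPerCellMean = as.numeric(recordsPerCellMean),
      noiseRecordProb = as.numeric(noiseRecordProb),
      seed = as.integer(seed), cellSize = as.numeric(cellSize))
}

#' Grid specification implied by a scenario
#'
#' @param scenario a [SyntheticScenario-class].
#' @return the [GridSpec-class] the generators emit coordinates on.
#' @export
scenarioGrid <- function(scenario) {
  gridSpec(cellSize = scenario@cellSize, originX = 0, originY = 0,
           nRows = scenario@gridRows, nCols = scenario@gridCols)
}

# near-square factor pair (br x bc >= nRegions not required; exact divisors)
.blockFactors <- function(nRegions, rows, cols) {
  divs <- which(nRegions %% seq_len(nRegions) == 0)
  pairs <- cbind(divs, nRegions / divs)
  target <- log(rows / cols)
  best <- which.min(abs(log(pairs[, 1] / pairs[, 2]) - target))
  pairs[best, ]
}

#' Planted region layout of a scenario
#'
#' Deterministic in the scenario parameters and seed. "blocks" partitions
#' the grid into contiguous rectangular bands; "voronoi" assigns each cell
#' to the nearest of nRegions seed cells (ties to the lower seed index).
#' Every cell belongs to exactly one planted region.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return a [RegionClassification-class] with labels "P01"..., covering
#'   every grid cell in row-major order.
#' @export
plantedRegions <- function(scenario) {
  nr <- scenario@gridRows; nc <- scenario@gridCols
  ij <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  if (scenario@regionLayout == "blocks") {
    f <- .blockFactors(scenario@nRegions, nr, nc)
    br <- f[1]; bc <- f[2]
    rowBand <- pmin(floor(ij$row * br / nr), br - 1L)
    colBand <- pmin(floor(ij$col * bc / nc), bc - 1L)
    region <- rowBand * bc + colBand + 1L
  } else {
    seeds <- withSeed(subSeed(scenario@seed, 1L), {
      idx <- sample.int(nr * nc, scenario@nRegions)
      cbind(row = (idx - 1L) %/% nc, col = (idx - 1L) %% nc)
    })
    d2 <- outer(ij$row, seeds[, "row"], `-`)^2 +
          outer(ij$col, seeds[, "col"], `-`)^2
    region <- max.col(-d2, ties.method = "first")
  }
  regionClassification(cellId(ij$row, ij$col), sprintf("P%02d", region),
                       provenance = list(source = "planted",
                                         layout = scenario@regionLayout))
}

# region adjacency (which planted regions share a cell border)
.regionAdjacency <- function(layout) {
  labs <- regionLabels(layout)
  adj <- cellAdjacency(names(labs))
  pairs <- unique(cbind(pmin(labs[adj[, 1]], labs[adj[, 2]]),
                        pmax(labs[adj[, 1]], labs[adj[, 2]])))
  pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
}

# Species pools: each region owns poolSizePerRegion species named after it;
# the first round(sharedFraction * poolSize) of each pool are shared into
# adjacent regions' available pools.
.speciesPools <- function(scenario, layout) {
  regions <- sort(unique(regionLabels(layout)))
  # binomial-style names so the taxon-normalization step of the ingest
  # path is the identity on synthetic data
  own <- lapply(regions, function(r) {
    sprintf("Synthgenus %s%03d", tolower(r),
            seq_len(scenario@poolSizePerRegion))
  })
  names(own) <- regions
  avail <- own
  nShared <- round(scenario@sharedFraction * scenario@poolSizePerRegion)
  if (nShared > 0 && length(regions) > 1L) {
    adj <- .regionAdjacency(layout)
    for (i in seq_len(nrow(adj))) {
      r1 <- adj[i, 1]; r2 <- adj[i, 2]
      avail[[r1]] <- union(avail[[r1]], own[[r2]][seq_len(nShared)])
      avail[[r2]] <- union(avail[[r2]], own[[r1]][seq_len(nShared)])
    }
  }
  list(own = own, avail = avail)
}

#' Planted community incidence (generator ground truth)
#'
#' The per-cell species communities the occurrence sampler draws from:
#' each species available to a cell's region is present with probability
#' \code{occupancyProb} (every draw independent; a cell left empty is given
#' one fallback species so no community is empty). This is the exact
#' incidence [generateOccurrences()] samples records from, so with
#' occupancy 1 and zero noise the gridded presence matrix equals it.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list: \code{community} (named list of species vectors per cell),
#'   \code{pools} (own/available pools per region), \code{layout}
#'   (planted [RegionClassification-class]).
#' @export
plantedCommunity <- function(scenario) {
  layout <- plantedRegions(scenario)
  pools <- .speciesPools(scenario, layout)
  labs <- regionLabels(layout)
  community <- withSeed(subSeed(scenario@seed, 2L), {
    lapply(names(labs), function(cell) {
      pool <- pools$avail[[labs[[cell]]]]
      keep <- pool[stats::runif(length(pool)) < scenario@occupancyProb]
      if (length(keep) == 0L) keep <- pool[sample.int(length(pool), 1L)]
      keep
    })
  })
  names(community) <- names(labs)
  list(community = community, pools = pools, layout = layout)
}

#' Generate synthetic occurrence records
#'
#' Records per cell follow a Poisson law with the scenario's mean; each
#' record's species is drawn uniformly from the cell's planted community,
#' or (with probability \code{noiseRecordProb}) uniformly from the global
#' pool regardless of region. Coordinates are cell centers plus uniform
#' jitter in the projected plane; with \code{geographic = TRUE} they are
#' inverse-projected to longitude/latitude so the full ingest path is
#' exercised.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param geographic emit lon/lat instead of planar x/y.
#' @return data.frame of records (species + coordinates) with the planted
#'   community in attribute \code{groundTruth}.
#' @export
generateOccurrences <- function(scenario, geographic = FALSE) {
  truth <- plantedCommunity(scenario)
  grid <- scenarioGrid(scenario)
  cells <- names(truth$community)
  rc <- cellRowCol(cells)
  globalPool <- sort(unique(unlist(truth$pools$own)))

  rec <- withSeed(subSeed(scenario@seed, 3L), {
    counts <- stats::rpois(length(cells), scenario@recordsPerCellMean)
    ci <- rep(seq_along(cells), counts)
    n <- length(ci)
    noise <- stats::runif(n) < scenario@noiseRecordProb
    species <- character(n)
    for (i in seq_along(cells)) {
      take <- which(ci == i & !noise)
      if (length(take)) {
        comm <- truth$community[[i]]
        species[take] <- comm[sample.int(length(comm), length(take),
                                         replace = TRUE)]
      }
    }
    if (any(noise)) {
      species[noise] <- globalPool[sample.int(length(globalPool), sum(noise),
                                              replace = TRUE)]
    }
    jx <- stats::runif(n, 0.01, 0.99)
    jy <- stats::runif(n, 0.01, 0.99)
    data.frame(species = species,
               x = (rc$col[ci] + jx) * scenario@cellSize,
               y = (rc$row[ci] + jy) * scenario@cellSize,
               stringsAsFactors = FALSE)
  })
  if (geographic) {
    ll <- albersInverse(rec$x, rec$y, grid@projection)
    rec <- data.frame(species = rec$species, lon = ll$lon, lat = ll$lat,
                      stringsAsFactors = FALSE)
  }
  attr(rec, "groundTruth") <- truth
  rec
}

#' Generate a distorted reference classification
#'
#' Returns the planted layout with \code{round(distortionFraction * nCells)}
#' randomly chosen cells relabelled to a different region's label (the
#' label of a random differing-label neighbouring cell when one exists,
#' otherwise a random other region). \code{distortionFraction = 0} returns
#' the planted layout exactly.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param distortionFraction proportion of cells to relabel, in [0, 1].
#' @return a [RegionClassification-class].
#' @export
generateReferenceClassification <- function(scenario, distortionFraction = 0) {
  if (distortionFraction < 0 || distortionFraction > 1) {
    stop("distortionFraction must lie in [0, 1]")
  }
  layout <- plantedRegions(scenario)
  labs <- regionLabels(layout)
  nDistort <- round(distortionFraction * length(labs))
  if (nDistort == 0L) {
    layout@provenance <- list(source = "reference", distortion = 0)
    return(layout)
  }
  adj <- cellAdjacency(names(labs))
  nbrs <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
  allRegions <- unique(labs)
  newLabs <- withSeed(subSeed(scenario@seed, 4L), {
    targets <- sample(names(labs), nDistort)
    out <- labs
    for (cell in targets) {
      nbLabs <- setdiff(unique(labs[nbrs[[cell]]]), labs[[cell]])
      if (length(nbLabs) == 0L) nbLabs <- setdiff(allRegions, labs[[cell]])
      out[[cell]] <- if (length(nbLabs) == 1L) nbLabs else sample(nbLabs, 1L)
    }
    out
  })
  regionClassification(names(newLabs), unname(newLabs),
                       provenance = list(source = "reference",
                                         distortion = distortionFraction))
}

#' Generate a synthetic environmental layer
#'
#' Cell value = linear row gradient + per-region offset + i.i.d. Gaussian
#' noise. The offsets are recorded in the result's attributes so the
#' expected sign of each region's Gi* score is known to callers.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param offsets numeric vector, one offset per planted region (in planted
#'   label order).
#' @param noiseSd nonnegative noise standard deviation.
#' @param gradientSlope value increment per grid row (0 = flat field).
#' @param name variable name for the resulting column.
#' @return an [EnvCellTable-class] with one variable, offsets in
#'   \code{attr(envValues(x), "offsets")}.
#' @export
generateEnvironment <- function(scenario, offsets, noiseSd = 0,
                                gradientSlope = 1, name = "var1") {
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  layout <- plantedRegions(scenario)
  labs <- regionLabels(layout)
  regions <- sort(unique(labs))
  if (length(offsets) != length(regions)) {
    stop("need exactly one offset per planted region (",
         length(regions), ")")
  }
  names(offsets) <- regions
  rc <- cellRowCol(names(labs))
  vals <- gradientSlope * rc$row + offsets[labs]
  if (noiseSd > 0) {
    vals <- vals + withSeed(subSeed(scenario@seed, 5L),
                            stats::rnorm(length(vals), 0, noiseSd))
  }
  m <- matrix(vals, ncol = 1, dimnames = list(names(labs), name))
  attr(m, "offsets") <- offsets
  new("EnvCellTable", values = m, grid = scenarioGrid(scenario))
}
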