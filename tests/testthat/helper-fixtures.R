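# Fixture builders used across the suite. Everything is generated in code;
# no data files.

# Build a SiteBySpeciesMatrix from a named list of species vectors, placing
# cells row-major on a 1 x length(communities) grid unless explicit cell
# ids (r###_c### form) are supplied as names.
makeSiteMatrix <- function(communities, records = NULL) {
  ids <- names(communities)
  if (is.null(ids) || !all(grepl("^r[0-9]+_c[0-9]+$", ids))) {
    ids <- phytoregions:::cellId(0L, seq_along(communities) - 1L)
    names(communities) <- ids
  }
  rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(species = communities[[i]], cell = ids[i])
  }))
  rc <- phytoregions:::cellRowCol(rows$cell)
  grid <- gridSpec(cellSize = 1, nRows = max(rc$row) + 1L,
                   nCols = max(rc$col) + 1L)
  recs <- data.frame(species = rows$species,
                     x = rc$col + 0.5, y = rc$row + 0.5)
  m <- gridRecords(recs, grid)
  if (!is.null(records)) {
    m@recordsPerCell <- as.integer(records[match(cellIds(m), ids)])
  }
  m
}

# Independent brute-force Simpson's beta from first principles.
bruteBeta <- function(si, sj) {
  si <- unique(si); sj <- unique(sj)
  a <- sum(si %in% sj)
  b <- length(si) - a
  c <- length(sj) - a
  if (a == 0) 1 else min(b, c) / (min(b, c) + a)
}

# Random incidence with no empty cells or species, as a list of species
# vectors per cell.
randomCommunities <- function(nCells, nSpecies, fillProb = 0.35) {
  species <- sprintf("s%03d", seq_len(nSpecies))
  repeat {
    sets <- lapply(seq_len(nCells), function(i) {
      species[stats::runif(nSpecies) < fillProb]
    })
    if (all(lengths(sets) > 0) &&
        length(unique(unlist(sets))) == nSpecies) return(sets)
  }
}

# Random symmetric dissimilarity matrix with distinct off-diagonal values
# (tie-free by construction).
randomTieFreeDissimilarity <- function(n) {
  npair <- n * (n - 1) / 2
  vals <- sample(seq_len(npair * 10), npair) / (npair * 10)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  dimnames(d) <- list(sprintf("L%02d", 1:n), sprintf("L%02d", 1:n))
  d
}

# Planted-recovery agreement for one scenario at k = planted count.
recoverScenario <- function(scenario) {
  occ <- generateOccurrences(scenario)
  m <- gridRecords(occ, scenarioGrid(scenario))
  cut <- cutRegions(wpgma(turnoverMatrix(m), m), k = scenario@nRegions)
  planted <- regionLabels(plantedRegions(scenario))
  got <- regionLabels(cut$classification)
  list(agreement = matchedAgreement(got[cellIds(m)], planted[cellIds(m)]),
       diagnostics = cut$diagnostics)
}
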