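# Synthetic scenario generators: determinism, planted structure, the
# reference distorter and the environmental layer builder.

test_that("invalid scenario parameters are rejected", {
  expect_error(syntheticScenario(occupancyProb = 0), "occupancyProb")
  expect_error(syntheticScenario(noiseRecordProb = 1), "noiseRecordProb")
  expect_error(syntheticScenario(sharedFraction = 1.2), "sharedFraction")
  expect_error(syntheticScenario(gridRows = 0), "positive")
  expect_error(syntheticScenario(recordsPerCellMean = -1), "recordsPerCellMean")
  expect_error(syntheticScenario(gridRows = 2, gridCols = 2, nRegions = 5),
               "nRegions")
})

test_that("identical seed and parameters reproduce identical records", {
  s <- syntheticScenario(gridRows = 4, gridCols = 4, nRegions = 2, seed = 42,
                         poolSizePerRegion = 10, recordsPerCellMean = 8)
  o1 <- generateOccurrences(s)
  o2 <- generateOccurrences(s)
  expect_identical(o1$species, o2$species)
  expect_identical(o1$x, o2$x)
  # a different seed changes the draw
  s2 <- syntheticScenario(gridRows = 4, gridCols = 4, nRegions = 2, seed = 43,
                          poolSizePerRegion = 10, recordsPerCellMean = 8)
  expect_false(identical(generateOccurrences(s2)$species, o1$species))
})

test_that("planted regions partition the grid into contiguous blocks", {
  for (nr in 2:6) {
    s <- syntheticScenario(gridRows = 6, gridCols = 8, nRegions = nr)
    layout <- plantedRegions(s)
    labs <- regionLabels(layout)
    expect_equal(length(labs), 48)
    expect_false(any(is.na(labs)))
    expect_equal(nRegions(layout), nr)
    adj <- phytoregions:::cellAdjacency(names(labs))
    for (r in unique(labs)) {
      cellsR <- names(labs)[labs == r]
      expect_equal(phytoregions:::largestComponent(cellsR, adj),
                   length(cellsR))
    }
  }
})

test_that("voronoi layouts cover the grid with the requested regions", {
  s <- syntheticScenario(gridRows = 10, gridCols = 10, nRegions = 4,
                         regionLayout = "voronoi", seed = 3)
  labs <- regionLabels(plantedRegions(s))
  expect_equal(nRegions(plantedRegions(s)), 4L)
  expect_identical(regionLabels(plantedRegions(s)), labs)  # deterministic
})

test_that("disjoint pools force beta = 1 between regions", {
  s <- syntheticScenario(gridRows = 4, gridCols = 4, nRegions = 2,
                         sharedFraction = 0, noiseRecordProb = 0,
                         occupancyProb = 1, poolSizePerRegion = 12,
                         recordsPerCellMean = 30, seed = 8)
  occ <- generateOccurrences(s)
  m <- gridRecords(occ, scenarioGrid(s))
  tm <- turnoverMatrix(m)
  planted <- regionLabels(plantedRegions(s))[cellIds(m)]
  cross <- outer(planted, planted, `!=`)
  expect_true(all(tm@beta[cross] == 1))
})

test_that("full occupancy without noise reproduces the planted incidence", {
  s <- syntheticScenario(gridRows = 3, gridCols = 4, nRegions = 2,
                         sharedFraction = 0.2, noiseRecordProb = 0,
                         occupancyProb = 1, poolSizePerRegion = 6,
                         recordsPerCellMean = 200, seed = 12)
  occ <- generateOccurrences(s)
  truth <- attr(occ, "groundTruth")
  m <- gridRecords(occ, scenarioGrid(s))
  # at 200 records/cell every community member is observed with near
  # certainty; the presence sets must equal the planted communities
  for (cell in cellIds(m)) {
    got <- speciesIds(m)[as.logical(presenceMatrix(m)[match(cell, cellIds(m)), ])]
    expect_setequal(got, truth$community[[cell]])
  }
})

test_that("single-pool beta matches a Monte-Carlo oracle of the sampling model", {
  # one region, full occupancy, no noise: both cells sample the same
  # 6-species pool through Poisson(5) multinomial draws. The oracle
  # simulates that model directly, independent of the generator code.
  pool <- 6; lambda <- 5
  set.seed(99)
  oracle <- replicate(20000, {
    na <- rpois(1, lambda); nb <- rpois(1, lambda)
    if (na == 0 || nb == 0) return(NA_real_)
    sa <- unique(sample.int(pool, na, replace = TRUE))
    sb <- unique(sample.int(pool, nb, replace = TRUE))
    a <- length(intersect(sa, sb))
    b <- length(sa) - a; c <- length(sb) - a
    if (a == 0) 1 else min(b, c) / (min(b, c) + a)
  })
  oracleMean <- mean(oracle, na.rm = TRUE)

  beta <- vapply(1:300, function(seed) {
    s <- syntheticScenario(gridRows = 1, gridCols = 2, nRegions = 1,
                           sharedFraction = 0, noiseRecordProb = 0,
                           occupancyProb = 1, poolSizePerRegion = pool,
                           recordsPerCellMean = lambda, seed = seed)
    occ <- generateOccurrences(s)
    m <- tryCatch(gridRecords(occ, scenarioGrid(s)), error = function(e) NULL)
    if (is.null(m) || length(cellIds(m)) < 2) return(NA_real_)
    turnoverMatrix(m)@beta[1, 2]
  }, 0)
  expect_lt(abs(mean(beta, na.rm = TRUE) - oracleMean), 0.04)
})

test_that("zero distortion returns the planted layout exactly", {
  s <- syntheticScenario(gridRows = 4, gridCols = 4, nRegions = 2)
  ref <- generateReferenceClassification(s, 0)
  expect_identical(regionLabels(ref), regionLabels(plantedRegions(s)))
  expect_error(generateReferenceClassification(s, 1.5), "distortionFraction")
})

test_that("distortion 0.25 on a 4x4 two-region grid relabels exactly 4 cells", {
  s <- syntheticScenario(gridRows = 4, gridCols = 4, nRegions = 2, seed = 31)
  ref <- generateReferenceClassification(s, 0.25)
  planted <- regionLabels(plantedRegions(s))
  expect_equal(sum(regionLabels(ref)[names(planted)] != planted), 4L)
})

test_that("a full flip of a two-region layout is a pure relabeling", {
  # with 2 regions every distorted cell takes the only other label, so
  # distortion 1 swaps the two labels everywhere; by hand enumeration the
  # overlap statistic (which is invariant to relabeling) must report 100
  s <- syntheticScenario(gridRows = 4, gridCols = 4, nRegions = 2, seed = 7)
  ref <- generateReferenceClassification(s, 1)
  planted <- plantedRegions(s)
  expect_true(all(regionLabels(ref) != regionLabels(planted)))
  expect_equal(overallAgreement(overlapAgreement(planted, ref)), 100)
})

test_that("environmental layers follow gradient + offset + noise", {
  s <- syntheticScenario(gridRows = 4, gridCols = 5, nRegions = 2, seed = 2)
  env <- generateEnvironment(s, offsets = c(0, 0), noiseSd = 0,
                             gradientSlope = 2)
  vals <- envValues(env)
  rc <- phytoregions:::cellRowCol(rownames(vals))
  expect_equal(unname(vals[, 1]), 2 * rc$row)
  expect_error(generateEnvironment(s, offsets = c(0, 0, 0)), "one offset per")
  expect_error(generateEnvironment(s, offsets = c(0, 0), noiseSd = -1),
               "nonnegative")
  # deterministic noise under the scenario seed
  e1 <- generateEnvironment(s, c(0, 0), noiseSd = 1)
  e2 <- generateEnvironment(s, c(0, 0), noiseSd = 1)
  expect_identical(envValues(e1), envValues(e2))
})

test_that("recovery degrades monotonically as pools blend together", {
  agree <- vapply(c(0, 0.45, 0.9), function(sf) {
    mean(vapply(1:6, function(seed) {
      s <- syntheticScenario(gridRows = 6, gridCols = 8, nRegions = 4,
                             sharedFraction = sf, noiseRecordProb = 0.02,
                             occupancyProb = 0.85, poolSizePerRegion = 30,
                             recordsPerCellMean = 30, seed = seed)
      recoverScenario(s)$agreement
    }, 0))
  }, 0)
  expect_true(all(diff(agree) <= 0.02))
  expect_gt(agree[1], agree[3])
})
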