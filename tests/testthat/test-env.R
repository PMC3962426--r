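# Environmental aggregation and the Getis-Ord Gi* statistic.

test_that("point values aggregate to arithmetic cell means", {
  grid <- gridSpec(cellSize = 10, nRows = 2, nCols = 2)
  pts <- data.frame(x = c(1, 2, 3, 4, 15), y = c(1, 2, 3, 4, 5),
                    temp = c(1, 2, 3, 4, 7))
  env <- aggregateEnv(pts, grid)
  v <- envValues(env)
  expect_equal(v["r000_c000", "temp"], 2.5)
  expect_equal(v["r000_c001", "temp"], 7)
  expect_true(is.na(v["r001_c000", "temp"]))  # explicit missing state
  # uniform field -> every covered cell mean equals the constant
  uni <- data.frame(x = runif(200, 0, 20), y = runif(200, 0, 20), v = 7)
  expect_true(all(envValues(aggregateEnv(uni, grid))[, "v"] == 7,
                  na.rm = TRUE))
  expect_error(aggregateEnv(data.frame(x = 100, y = 100, v = 1), grid),
               "inside the grid")
})

test_that("cell means of a linear gradient match the closed form", {
  s <- syntheticScenario(gridRows = 5, gridCols = 4, nRegions = 2, seed = 9)
  env <- generateEnvironment(s, offsets = c(0, 0), noiseSd = 0,
                             gradientSlope = 3)
  # closed form: value = slope * row index
  rc <- phytoregions:::cellRowCol(rownames(envValues(env)))
  expect_equal(unname(envValues(env)[, 1]), 3 * rc$row, tolerance = 1e-12)
})

test_that("Gi* matches the closed form on the 4-cell fixture", {
  grid <- gridSpec(cellSize = 1, nRows = 1, nCols = 4)
  cells <- phytoregions:::cellId(0L, 0:3)
  env <- new("EnvCellTable",
             values = matrix(c(0, 0, 10, 10), 4,
                             dimnames = list(cells, "v")),
             grid = grid)
  res <- giStar(env, cells[3:4], "v")
  expect_equal(res$z, 10 / (5 * sqrt(4 / 3)), tolerance = 1e-12)
  expect_equal(res$z, 1.7320508, tolerance = 1e-7)
  expect_false(res$significant)
  # a region whose mean equals the global mean scores exactly 0
  res0 <- giStar(env, cells[c(1, 3)], "v")
  expect_equal(res0$z, 0)
})

test_that("degenerate Gi* inputs raise errors", {
  grid <- gridSpec(cellSize = 1, nRows = 1, nCols = 4)
  cells <- phytoregions:::cellId(0L, 0:3)
  env <- new("EnvCellTable",
             values = matrix(c(0, 0, 10, 10), 4,
                             dimnames = list(cells, "v")),
             grid = grid)
  expect_error(giStar(env, cells, "v"), "whole support")
  flat <- new("EnvCellTable",
              values = matrix(5, 4, dimnames = list(cells, "v")), grid = grid)
  expect_error(giStar(flat, cells[1:2], "v"), "zero global variance")
})

test_that("Gi* is invariant to location and scale shifts", {
  set.seed(23)
  grid <- gridSpec(cellSize = 1, nRows = 5, nCols = 5)
  cells <- phytoregions:::cellId(rep(0:4, each = 5), rep(0:4, 5))
  x <- rnorm(25)
  region <- cells[1:6]
  mk <- function(v) new("EnvCellTable",
                        values = matrix(v, 25, dimnames = list(cells, "v")),
                        grid = grid)
  z0 <- giStar(mk(x), region, "v")$z
  expect_equal(giStar(mk(x + 100), region, "v")$z, z0, tolerance = 1e-9)
  expect_equal(giStar(mk(x * 37), region, "v")$z, z0, tolerance = 1e-9)
})

test_that("two complementary regions score opposite signs", {
  set.seed(29)
  grid <- gridSpec(cellSize = 1, nRows = 4, nCols = 5)
  cells <- phytoregions:::cellId(rep(0:3, each = 5), rep(0:4, 4))
  env <- new("EnvCellTable",
             values = matrix(rnorm(20), 20, dimnames = list(cells, "v")),
             grid = grid)
  z1 <- giStar(env, cells[1:8], "v")$z
  z2 <- giStar(env, cells[9:20], "v")$z
  expect_lt(z1 * z2, 0)
})

test_that("a planted offset region is significant and matches the closed form", {
  s <- syntheticScenario(gridRows = 4, gridCols = 6, nRegions = 2, seed = 4)
  env <- generateEnvironment(s, offsets = c(10, 0), noiseSd = 0,
                             gradientSlope = 0)
  labs <- regionLabels(plantedRegions(s))
  cellsP1 <- names(labs)[labs == "P01"]
  res <- giStar(env, cellsP1, "var1")
  # closed form on a two-valued field
  x <- envValues(env)[, 1]
  n <- length(x); m <- length(cellsP1)
  zExp <- (sum(x[cellsP1]) - mean(x) * m) /
    (stats::sd(x) * sqrt((n - 1) / n) * sqrt((n * m - m^2) / (n - 1)))
  expect_equal(res$z, zExp, tolerance = 1e-12)
  expect_gt(res$z, 2)
  expect_true(res$significant)
})

test_that("region profiles find the planted variable and flag degenerates", {
  s <- syntheticScenario(gridRows = 4, gridCols = 6, nRegions = 2, seed = 6)
  planted <- plantedRegions(s)
  e1 <- generateEnvironment(s, offsets = c(10, 0), noiseSd = 0.5,
                            gradientSlope = 0, name = "offsetVar")
  e2 <- generateEnvironment(s, offsets = c(0, 0), noiseSd = 1,
                            gradientSlope = 0, name = "noiseVar")
  env <- new("EnvCellTable",
             values = cbind(envValues(e1), envValues(e2)),
             grid = scenarioGrid(s))
  prof <- regionEnvProfile(env, planted)
  expect_equal(nrow(prof), 4)
  extreme <- attr(prof, "mostExtreme")
  expect_true(all(extreme == "offsetVar"))
  zs <- prof$z[prof$variable == "offsetVar"]
  expect_lt(zs[1] * zs[2], 0)  # opposite signs for the two regions

  # one region spanning the whole grid degenerates without aborting
  whole <- regionClassification(rownames(envValues(env)),
                                rep("all", nrow(envValues(env))))
  profW <- regionEnvProfile(env, whole)
  expect_true(all(is.na(profW$z)))
})

test_that("the null calibration of |z| > 2 is near the nominal tail mass", {
  set.seed(37)
  n <- 60; m <- 12
  x <- rnorm(n)
  cells <- sprintf("r%03d_c%03d", rep(0:5, each = 10), rep(0:9, 6))
  env <- new("EnvCellTable",
             values = matrix(x, n, dimnames = list(cells, "v")),
             grid = gridSpec(cellSize = 1, nRows = 6, nCols = 10))
  hits <- replicate(2000, {
    abs(giStar(env, sample(cells, m), "v")$z) > 2
  })
  expect_lt(abs(mean(hits) - 0.046), 0.02)
})
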