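# CWE, tie-broken WPGMA, region extraction, Newick serialization.

test_that("CWE follows the range-fraction definition", {
  # cell a: taxon A endemic to a; taxon B in 4 cells total
  comm <- list(c("A", "B"), "B", "B", "B")
  m <- makeSiteMatrix(stats::setNames(comm, NULL))
  sc <- cwe(cellIds(m)[1], m)
  expect_equal(sc@we, 1.25)
  expect_equal(sc@richness, 2L)
  expect_equal(sc@cwe, 0.625)

  # the whole grid always scores CWE = 1
  expect_equal(cwe(cellIds(m), m)@cwe, 1)

  # every taxon occurring twice outside for each inside occurrence -> 1/3
  comm3 <- list(c("X", "Y"), c("X", "Y"), c("X", "Y"), "Z", "Z", "Z")
  m3 <- makeSiteMatrix(stats::setNames(comm3, NULL))
  expect_equal(cwe(cellIds(m3)[1], m3)@cwe, 1 / 3)

  expect_error(cwe("nope", m), "subset")
})

test_that("WPGMA reproduces the hand-computed 3-leaf merge sequence", {
  d <- matrix(c(0, .2, .6, .2, 0, .4, .6, .4, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  dend <- wpgma(d)
  expect_equal(dend@height, c(0.2, 0.5))
  expect_equal(dend@merge[1, ], c(-1L, -2L))   # (x, y) first
  expect_equal(toNewick(dend), "((x:0.2,y:0.2):0.3,z:0.5);")
})

test_that("tie-free instances match the reference WPGMA implementation", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    d <- randomTieFreeDissimilarity(n)
    ours <- stats::cophenetic(as.hclust(wpgma(d)))
    ref <- stats::cophenetic(stats::hclust(stats::as.dist(d),
                                           method = "mcquitty"))
    expect_equal(as.matrix(ours), as.matrix(ref), tolerance = 1e-12)
  }
})

test_that("heights are monotone and merges respect the dissimilarity scale", {
  set.seed(55)
  for (rep in 1:5) {
    m <- makeSiteMatrix(stats::setNames(randomCommunities(12, 40), NULL))
    dend <- wpgma(turnoverMatrix(m), m)
    expect_false(is.unsorted(dend@height))
    expect_true(all(dend@height >= 0 & dend@height <= 1))
  }
})

test_that("tied merges resolve to the highest union CWE, then lexicographic", {
  # six cells built so that several pairs tie at beta = 0.5 while their
  # union CWE differs, with the (A, B) union maximal by construction:
  #   A = {s1, a1}, B = {s1, b1}           union CWE = 1
  #   C = {s2, c1}, D = {s2, d1}           union CWE = 2/3
  #   E = {c1, e1}, F = {d1, f1}           (C,E)/(D,F) unions CWE = 5/6
  comm <- list(c("s1", "a1"), c("s1", "b1"),
               c("s2", "c1"), c("s2", "d1"),
               c("c1", "e1"), c("d1", "f1"))
  m <- makeSiteMatrix(stats::setNames(comm, NULL))
  tm <- turnoverMatrix(m)
  tied <- which(abs(tm@beta - 0.5) < 1e-12 & upper.tri(tm@beta), arr.ind = TRUE)
  expect_gte(nrow(tied), 4)  # the tie really is saturated
  dend <- wpgma(tm, m)
  expect_equal(sort(dend@merge[1, ]), c(-2L, -1L))  # A and B merge first

  # with the tie-breaker starved of incidence data the rule is lexicographic
  dend2 <- wpgma(tm@beta)
  expect_equal(sort(dend2@merge[1, ]), c(-2L, -1L))
})

test_that("tie-saturated input yields byte-identical dendrograms on repeat runs", {
  # 20 mutually disjoint cells: all pairwise beta = 1 and all union CWE = 1,
  # so both tie-break layers are exercised down to the lexicographic rule
  comm <- lapply(1:20, function(i) sprintf("p%02d_%d", i, 1:2))
  m <- makeSiteMatrix(stats::setNames(comm, NULL))
  tm <- turnoverMatrix(m)
  first <- toNewick(wpgma(tm, m))
  for (i in 1:20) expect_identical(toNewick(wpgma(tm, m)), first)
})

test_that("cophenetic heights equal brute-force WPGMA recursion", {
  # ultrametric consistency on a small random instance
  set.seed(77)
  d <- randomTieFreeDissimilarity(8)
  dend <- wpgma(d)
  co <- as.matrix(stats::cophenetic(as.hclust(dend)))
  # brute force: replay the merges averaging pairwise leaf distances with
  # WPGMA weights (each child cluster weighs 1/2 regardless of size)
  sets <- phytoregions:::.nodeLeafSets(dend)
  wpgmaDist <- function(setA, setB) {
    if (length(setA) == 1 && length(setB) == 1) return(d[setA, setB])
    if (length(setA) < length(setB)) { tmp <- setA; setA <- setB; setB <- tmp }
    node <- which(vapply(sets, function(s) setequal(s, setA), TRUE))[1]
    kids <- dend@merge[node, ]
    grab <- function(v) if (v < 0) -v else sets[[v]]
    (wpgmaDist(grab(kids[1]), setB) + wpgmaDist(grab(kids[2]), setB)) / 2
  }
  for (k in seq_along(dend@height)) {
    kids <- dend@merge[k, ]
    grab <- function(v) if (v < 0) -v else sets[[v]]
    expect_equal(dend@height[k], wpgmaDist(grab(kids[1]), grab(kids[2])),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(co - t(co)) < 1e-15))
})

test_that("cutting at k recovers the forced partitions", {
  d <- matrix(c(0, .2, .6, .2, 0, .4, .6, .4, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  dend <- wpgma(d)
  cut2 <- cutRegions(dend, k = 2)
  lab <- regionLabels(cut2$classification)
  expect_equal(lab[["x"]], lab[["y"]])
  expect_false(lab[["x"]] == lab[["z"]])

  cut3 <- cutRegions(dend, k = 3)
  expect_equal(nRegions(cut3$classification), 3L)

  expect_error(cutRegions(dend, k = 4), "k must lie")
  expect_error(cutRegions(dend), "exactly one")
  expect_error(cutRegions(dend, k = 2, minBranch = 0.1), "exactly one")
})

test_that("minBranch mode reports maximal well-separated clusters", {
  d <- matrix(c(0, .2, .6, .2, 0, .4, .6, .4, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  dend <- wpgma(d)
  # (x,y) subtends 0.3, leaf z subtends 0.5: both pass at 0.25
  cut <- cutRegions(dend, minBranch = 0.25)
  lab <- regionLabels(cut$classification)
  expect_equal(lab[["x"]], lab[["y"]])
  expect_false(is.na(lab[["z"]]))
  expect_equal(nRegions(cut$classification), 2L)
  # at 0.4 only the z leaf qualifies; x and y stay unlabeled
  cut2 <- cutRegions(dend, minBranch = 0.4)
  lab2 <- regionLabels(cut2$classification)
  expect_true(is.na(lab2[["x"]]) && is.na(lab2[["y"]]))
  expect_false(is.na(lab2[["z"]]))
})

test_that("cut diagnostics report branch length and grid contiguity", {
  s <- syntheticScenario(gridRows = 4, gridCols = 6, nRegions = 2,
                         sharedFraction = 0, noiseRecordProb = 0,
                         occupancyProb = 1, poolSizePerRegion = 20,
                         recordsPerCellMean = 40, seed = 5)
  r <- recoverScenario(s)
  expect_true(all(r$diagnostics$contiguity == 1))
  expect_true(all(r$diagnostics$branchLength >= 0))
  expect_equal(sum(r$diagnostics$size), 24)
})

test_that("k = leaf count gives every cell its own region", {
  d <- randomTieFreeDissimilarity(6)
  cut <- cutRegions(wpgma(d), k = 6)
  expect_equal(nRegions(cut$classification), 6L)
})

test_that("Newick output round-trips through a standard parser", {
  skip_if_not_installed("ape")
  set.seed(202)
  for (rep in 1:5) {
    n <- sample(4:15, 1)
    dend <- wpgma(randomTieFreeDissimilarity(n))
    tr <- ape::read.tree(text = toNewick(dend))
    expect_equal(sort(tr$tip.label), sort(dend@labels))
    # cophenetic structure survives the round trip (tip-to-tip path length
    # in an ultrametric tree is twice the LCA height)
    co1 <- as.matrix(stats::cophenetic(as.hclust(dend)))
    co2 <- ape::cophenetic.phylo(tr)[rownames(co1), colnames(co1)]
    expect_equal(2 * co1, co2, tolerance = 1e-9)
  }
  expect_equal(toNewick(wpgma(matrix(0, 1, 1, dimnames = list("x", "x")))),
               "x:0.0;")
})
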