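test_that("four areas are solved by exact enumeration of the three topologies", {
  set.seed(1)
  tr <- ape::rtree(4); tr$edge.length <- rep(0.3, nrow(tr$edge))
  x <- simulateMatrix(tr, 50, seed = 2)
  allt <- allTopologies(areaNames(x))
  bestEx <- min(vapply(allt, function(t) fitchScore(t, x)$length, integer(1)))
  sr <- treeSearch(x, "parsimony", nStarts = 2, seed = 1)
  expect_equal(sr$score, bestEx)
})

test_that("likelihood search matches exhaustive topology evaluation", {
  set.seed(14)
  for (i in 1:2) {
    tr <- ape::rtree(5); tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.6)
    x <- simulateMatrix(tr, 60, seed = 40 + i)
    allt <- allTopologies(areaNames(x))
    ex <- vapply(allt, function(t) mkFit(t, x, gamma = FALSE)$logLik, numeric(1))
    sr <- treeSearch(x, "likelihood", gamma = FALSE, nStarts = 2,
                     swap = "spr", seed = i)
    expect_equal(sr$score, max(ex), tolerance = 1e-6)
  }
})

test_that("search is reproducible from its seed and reports verifiable scores", {
  set.seed(77)
  inst <- randomInstance(8, 40)
  a <- treeSearch(inst$x, "parsimony", nStarts = 3, swap = "spr", seed = 9)
  b <- treeSearch(inst$x, "parsimony", nStarts = 3, swap = "spr", seed = 9)
  expect_equal(a$score, b$score)
  expect_identical(lapply(a$trees, paeML:::.topoKey),
                   lapply(b$trees, paeML:::.topoKey))
  # every reported tree really has the claimed score, recomputed independently
  for (tr in a$trees)
    expect_equal(fitchScore(tr, inst$x)$length, a$score)
})

test_that("rearrangement neighbourhoods have the known sizes and nest properly", {
  set.seed(3)
  for (n in c(5, 6, 7)) {
    tr <- paeML:::.anchorRoot(ape::unroot(ape::rtree(n)), "t1")
    nni <- paeML:::.nniNeighbors(tr)
    spr <- paeML:::.sprNeighbors(tr)
    expect_length(nni, 2 * (n - 3))
    expect_length(spr, 2 * (n - 3) * (2 * n - 7))
    k0 <- paeML:::.topoKey(tr)
    nniK <- vapply(nni, paeML:::.topoKey, character(1))
    sprK <- vapply(spr, paeML:::.topoKey, character(1))
    expect_false(k0 %in% c(nniK, sprK))          # self excluded
    expect_true(all(nniK %in% sprK))             # NNI is a subset of SPR
    expect_equal(anyDuplicated(sprK), 0L)        # all distinct topologies
  }
})

test_that("SPR search is never beaten by NNI search on the same instance", {
  set.seed(31)
  for (i in 1:3) {
    inst <- randomInstance(7, 30)
    nni <- treeSearch(inst$x, "parsimony", nStarts = 2, swap = "nni", seed = i)
    spr <- treeSearch(inst$x, "parsimony", nStarts = 2, swap = "spr", seed = i)
    expect_lte(spr$score, nni$score)
  }
})

test_that("parsimony search never misses the generating topology's score", {
  set.seed(8)
  tr <- ape::rtree(9); tr$edge.length <- runif(nrow(tr$edge), 0.2, 0.6)
  x <- simulateMatrix(tr, 300, seed = 3)
  sr <- treeSearch(x, "parsimony", nStarts = 3, swap = "spr", seed = 4)
  expect_lte(sr$score, fitchScore(tr, x)$length)
})

test_that("bootstrap of a perfectly congruent matrix yields all-100 supports", {
  tr5 <- readAreaTree("((A,B),(C,(D,E)));")
  base <- cbind(c(1, 1, 0, 0, 0), c(0, 0, 0, 1, 1), c(1, 1, 1, 0, 0))
  rownames(base) <- c("A", "B", "C", "D", "E")
  m <- base[, rep(1:3, each = 50)]
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  x <- taxonAreaMatrix(m)
  bs <- bootstrapSearch(x, "parsimony", B = 15, nStarts = 2, seed = 6)
  sup <- suppressWarnings(as.numeric(bs$best$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  # only internal nodes carry labels: trivial (tip) splits are not reported
  expect_length(bs$best$node.label, bs$best$Nnode)
  # determinism
  bs2 <- bootstrapSearch(x, "parsimony", B = 15, nStarts = 2, seed = 6)
  expect_identical(bs$best$node.label, bs2$best$node.label)
})
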