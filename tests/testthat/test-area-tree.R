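test_that("all-zero outgroup row is appended without touching the data", {
  x <- lvvFixture(50, 3, seed = 4)
  xo <- addAllZeroOutgroup(x)
  expect_equal(dim(xo), dim(x) + c(1L, 0L))
  expect_equal(sum(presence(xo)["ROOT", ]), 0)
  expect_identical(presence(xo)[areaNames(x), ], presence(x))
  expect_error(addAllZeroOutgroup(x, "BOG"), "collision")

  x0 <- taxonAreaMatrix(matrix(0L, 2, 0, dimnames = list(c("A", "B"), NULL)))
  expect_equal(dim(addAllZeroOutgroup(x0)), c(3L, 0L))
})

test_that("Lundberg rooting picks the least-occupied area at the branch midpoint", {
  x <- lvvFixture(120, 6, seed = 11)
  occ <- rowSums(presence(x))
  expect_equal(names(which.min(occ)), "BOG")
  set.seed(1)
  tr <- ape::rtree(13)
  tr$tip.label <- areaNames(x)
  un <- ape::unroot(tr)
  lb <- lundbergRoot(un, x)
  expect_true(ape::is.rooted(lb))
  # BOG hangs directly off the root
  root <- length(lb$tip.label) + 1L
  rootKids <- lb$edge[lb$edge[, 1] == root, 2]
  expect_true(match("BOG", lb$tip.label) %in% rootKids)
  # rerooting never changes the unrooted topology or path lengths
  expect_equal(rfDistance(lb, un), 0L)
  d1 <- ape::cophenetic.phylo(un); d2 <- ape::cophenetic.phylo(lb)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-12)
  # midpoint: the two root edges split BOG's pendant edge evenly
  pend <- un$edge.length[un$edge[, 2] == match("BOG", un$tip.label)]
  eTip <- lb$edge.length[lb$edge[, 1] == root &
                         lb$edge[, 2] == match("BOG", lb$tip.label)]
  expect_equal(eTip, pend / 2)

  tie <- taxonAreaMatrix(matrix(1L, 13, 2,
    dimnames = list(areaNames(x), c("s1", "s2"))))
  expect_error(lundbergRoot(un, tie), "tie for minimum occurrence")
})

test_that("majority-rule consensus annotates bipartition frequencies", {
  t1 <- readAreaTree("((A,B),(C,D));")
  cons1 <- majorityConsensus(rep(list(t1), 10))
  expect_equal(rfDistance(cons1, t1), 0L)
  sup <- suppressWarnings(as.numeric(cons1$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  t2 <- readAreaTree("((A,C),(B,D));")
  cons2 <- majorityConsensus(c(rep(list(t1), 6), rep(list(t2), 4)))
  sup2 <- suppressWarnings(as.numeric(cons2$node.label))
  expect_true(60 %in% sup2)          # the {A,B} clade survives at 60%
  expect_equal(rfDistance(cons2, t1), 0L)

  # three mutually incompatible resolutions collapse to a polytomy
  t3 <- readAreaTree("((A,D),(B,C));")
  cons3 <- majorityConsensus(c(rep(list(t1), 3), rep(list(t2), 3), rep(list(t3), 3)))
  expect_true(ape::Nnode(cons3) < ape::Nnode(ape::unroot(t1)) + 1)
  expect_error(majorityConsensus(list(t1, readAreaTree("((A,B),(C,E));"))),
               "mismatched tip sets")
})

test_that("RF distance counts symmetric bipartition differences", {
  t1 <- readAreaTree("((A,B),(C,D));")
  t2 <- readAreaTree("((A,C),(B,D));")
  expect_equal(rfDistance(t1, t1), 0L)
  expect_equal(rfDistance(t1, t2), 2L)
  set.seed(42)
  for (i in 1:10) {
    a <- ape::rtree(7); b <- ape::rtree(7)
    b$tip.label <- sample(a$tip.label)
    expect_identical(rfDistance(a, b), rfDistance(b, a))
  }
  expect_error(rfDistance(t1, readAreaTree("((A,B),(C,E));")), "mismatched")
})
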