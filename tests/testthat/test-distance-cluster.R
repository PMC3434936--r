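test_that("area distances follow the mismatch and Jaccard definitions", {
  m <- rbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0), C = c(0, 0, 1, 1),
             D = c(1, 0, 1, 0))
  colnames(m) <- sprintf("s%d", 1:4)
  x <- taxonAreaMatrix(m)
  dh <- areaDistance(x, "hamming")
  dj <- areaDistance(x, "jaccard")
  expect_equal(dh["A", "B"], 0); expect_equal(dj["A", "B"], 0)
  expect_equal(dh["A", "C"], 1); expect_equal(dj["A", "C"], 1)
  expect_equal(dh["A", "D"], 0.5)
  expect_equal(dj["A", "D"], 1 - 1/3, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(dh)))
  expect_equal(diag(dh), setNames(rep(0, 4), rownames(m)))
  # both-empty convention for jaccard
  me <- rbind(A = c(0, 0), B = c(0, 0), C = c(1, 1))
  colnames(me) <- c("s1", "s2")
  expect_equal(areaDistance(taxonAreaMatrix(me), "jaccard")["A", "B"], 0)
})

test_that("UPGMA reproduces hand agglomeration and is ultrametric", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  up <- upgmaTree(d)
  expect_true(ape::is.ultrametric(up))
  # (A,B) joined at height 1, C at height 3
  cp <- ape::cophenetic.phylo(up)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 6)
  depth <- max(ape::node.depth.edgelength(up))
  expect_equal(depth, 3)

  # an already-ultrametric input is reproduced exactly
  set.seed(2)
  tr <- ape::rcoal(6)
  d2 <- ape::cophenetic.phylo(tr)
  up2 <- upgmaTree(d2)
  expect_equal(ape::cophenetic.phylo(up2)[rownames(d2), colnames(d2)], d2,
               tolerance = 1e-9)
})

test_that("UPGMA is invariant under area permutation and ultrametric on random input", {
  set.seed(12)
  for (i in 1:5) {
    x <- lvvFixture(60, 4, seed = i)
    d <- areaDistance(x)
    up <- upgmaTree(d)
    expect_true(ape::is.ultrametric(up, tol = 1e-9))
    perm <- sample(rownames(d))
    up2 <- upgmaTree(d[perm, perm])
    expect_equal(rfDistance(up, up2), 0L)
    expect_equal(sort(ape::cophenetic.phylo(up2)[rownames(d), rownames(d)]),
                 sort(ape::cophenetic.phylo(up)[rownames(d), rownames(d)]),
                 tolerance = 1e-12)
    # ultrametric three-point condition on all triples
    cp <- ape::cophenetic.phylo(up)
    nm <- rownames(cp)
    for (tri in utils::combn(nm, 3, simplify = FALSE)) {
      dd <- sort(c(cp[tri[1], tri[2]], cp[tri[1], tri[3]], cp[tri[2], tri[3]]))
      expect_lte(dd[3], dd[2] + 1e-9)
    }
  }
})

test_that("the fixture's UPGMA dendrogram separates the river-valley group", {
  x <- lvvFixture(400, 10, seed = 5)
  up <- upgmaTree(areaDistance(x))
  # the river-valley/delta areas cluster together (X, the area adjacent to
  # the valley group on the generating tree, may phenetically join them);
  # neither BOG nor BAC nor the steppe pairs intrude
  valley <- c("P", "BK", "ZIB", "XE", "AH", "BC")
  mrca <- ape::getMRCA(up, valley)
  got <- ape::extract.clade(up, mrca)$tip.label
  expect_true(all(valley %in% got))
  expect_true(all(got %in% c(valley, "X")))
  baer <- ape::extract.clade(up, ape::getMRCA(up, c("ZIB", "BK")))
  expect_setequal(baer$tip.label, c("ZIB", "BK"))
  steppe <- ape::extract.clade(up, ape::getMRCA(up, c("VP", "ZP")))
  expect_true(all(steppe$tip.label %in% c("VP", "ZP", "A", "C", "X", "BAC")))
})
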