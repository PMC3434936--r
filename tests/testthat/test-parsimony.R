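test_that("Fitch length handles textbook cases", {
  tr <- readAreaTree("((A,B),(C,D));")
  x1 <- taxonAreaMatrix(rbind(A = 1, B = 1, C = 1, D = 1), species = "s1")
  expect_equal(suppressWarnings(fitchScore(tr, x1))$length, 0L)
  x2 <- taxonAreaMatrix(rbind(A = 1, B = 1, C = 0, D = 0), species = "s1")
  expect_equal(fitchScore(tr, x2)$length, 1L)
  x3 <- taxonAreaMatrix(rbind(A = 1, B = 0, C = 1, D = 0), species = "s1")
  expect_equal(fitchScore(tr, x3)$length, 2L)
  expect_error(fitchScore(readAreaTree("((A,B,C),D,E);"),
    taxonAreaMatrix(matrix(0L, 5, 1,
      dimnames = list(c("A", "B", "C", "D", "E"), "s1")))), "polytomy")
})

test_that("Fitch length agrees with phangorn and is rooting/permutation invariant", {
  set.seed(5)
  for (i in 1:15) {
    inst <- randomInstance(sample(5:8, 1), 12)
    sc <- fitchScore(inst$tree, inst$x)
    dat <- phangorn::phyDat(inst$m, type = "USER", levels = c(0, 1))
    expect_equal(sc$length, as.integer(phangorn::fitch(inst$tree, dat)))
    expect_equal(sum(sc$steps), sc$length)
    un <- ape::unroot(inst$tree)
    re <- ape::root(un, outgroup = sample(un$tip.label, 1), resolve.root = TRUE)
    expect_equal(fitchScore(re, inst$x)$length, sc$length)
    perm <- inst$x[sample(areaNames(inst$x)), ]
    expect_equal(fitchScore(inst$tree, perm)$length, sc$length)
    # per-character bounds m_i <= s_i <= g_i
    expect_true(all(sc$steps >= sc$minSteps))
    expect_true(all(sc$steps <= sc$maxSteps | sc$maxSteps == 0))
  }
})

test_that("minimum length over all topologies matches exhaustive search", {
  set.seed(9)
  for (i in 1:5) {
    inst <- randomInstance(6, 10)
    allt <- allTopologies(rownames(inst$m))
    bestEx <- min(vapply(allt, function(t) fitchScore(t, inst$x)$length,
                         integer(1)))
    sr <- treeSearch(inst$x, "parsimony", nStarts = 3, swap = "spr", seed = i)
    expect_equal(sr$score, bestEx)
  }
})

test_that("CI and RI follow the ensemble formulas including degenerate cases", {
  # 5-tip character forced onto a discordant topology: s=2, m=1, g=2
  tr <- readAreaTree("((t1,t3),(t2,(t4,t5)));")
  m <- matrix(c(1, 1, 0, 0, 1), 5, 1, dimnames = list(paste0("t", 1:5), "s1"))
  sc <- fitchScore(tr, taxonAreaMatrix(m))
  expect_equal(unname(sc$steps), 2)
  expect_equal(unname(sc$minSteps), 1)
  expect_equal(unname(sc$maxSteps), 2)
  expect_equal(sc$ci, 0.5)
  expect_equal(sc$ri, 0)
  # homoplasy-free matrix on its generating topology
  tr2 <- readAreaTree("((A,B),(C,D));")
  m2 <- cbind(s1 = c(1, 1, 0, 0), s2 = c(0, 0, 1, 1))
  rownames(m2) <- c("A", "B", "C", "D")
  sc2 <- fitchScore(tr2, taxonAreaMatrix(m2))
  expect_equal(sc2$ci, 1); expect_equal(sc2$ri, 1)
  # degenerate conventions
  suppressWarnings(expect_warning(ciRi(0, 0, 0), "CI undefined"))
  expect_equal(suppressWarnings(ciRi(0, 0, 0)$ci), 1)
  expect_warning(ciRi(c(1), c(1), c(1)), "RI undefined")
  expect_equal(suppressWarnings(ciRi(c(1), c(1), c(1))$ri), 1)
})

test_that("all-zero columns never change tree length", {
  set.seed(2)
  inst <- randomInstance(7, 25)
  base <- fitchScore(inst$tree, inst$x)$length
  for (n in c(10, 100)) {
    aug <- addExtinctTaxa(inst$x, n)
    expect_equal(fitchScore(inst$tree, aug)$length, base)
  }
})
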