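test_that("transition probabilities take the closed two-state form", {
  expect_equal(transitionProbability(0), diag(2), ignore_attr = TRUE)
  expect_equal(max(abs(transitionProbability(1e6) - 0.5)), 0, tolerance = 1e-12)
  # independent oracle: matrix exponential of the rate matrix
  Q <- matrix(c(-1, 1, 1, -1), 2, 2)
  for (t in c(0.1, 0.5, 2)) for (r in c(0.3, 1, 4)) {
    P <- as.matrix(Matrix::expm(Q * r * t))
    expect_equal(unname(transitionProbability(t, r)), P, tolerance = 1e-12)
  }
  expect_equal(transitionProbability(0.5)[1, 2], 0.5 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_error(transitionProbability(-1), ">= 0")
  # rows sum to one, P(same) >= 1/2
  P <- transitionProbability(0.7, 1.3)
  expect_equal(rowSums(P), c("0" = 1, "1" = 1))
  expect_true(all(diag(P) >= 0.5))
})

test_that("discrete gamma categories average to unit rate and match phangorn", {
  for (a in c(0.1, 0.5, 2, 20)) {
    r <- gammaCategoryRates(a, 4)
    expect_equal(mean(r), 1)
    expect_equal(r, phangorn::discrete.gamma(a, 4), tolerance = 1e-9)
  }
  expect_equal(gammaCategoryRates(0.5, 1), 1)
})

test_that("pruning log-likelihood matches closed forms on tiny trees", {
  # constant-0 character on zero branch lengths: only the root prior remains
  tr0 <- readAreaTree("(A:0,B:0);")
  m0 <- taxonAreaMatrix(rbind(A = 0, B = 0), species = "sp1")
  expect_equal(mkLogLik(tr0, m0)$logLik, log(0.5), tolerance = 1e-12)
  # two tips in different states across total path 0.5
  tr <- readAreaTree("(A:0.2,B:0.3);")
  m <- taxonAreaMatrix(rbind(A = 0, B = 1), species = "sp1")
  expect_equal(mkLogLik(tr, m)$logLik, log(0.5 * 0.5 * (1 - exp(-1))),
               tolerance = 1e-12)
  expect_equal(exp(mkLogLik(tr, m)$siteLogLik[["sp1"]]),
               0.5 * 0.5 * (1 - exp(-1)), tolerance = 1e-12)
})

test_that("pruning equals brute-force ancestral enumeration, any rooting", {
  set.seed(101)
  for (i in 1:20) {
    inst <- randomInstance(sample(4:6, 1), 12)
    got <- mkLogLik(inst$tree, inst$x)
    expect_equal(got$logLik, bruteLogLik(inst$tree, inst$m), tolerance = 1e-10)
    expect_equal(got$logLik, sum(got$siteLogLik))
    # likelihood is invariant under rerooting of the reversible chain
    un <- ape::unroot(inst$tree)
    re <- ape::root(un, outgroup = sample(un$tip.label, 1), resolve.root = TRUE)
    expect_equal(mkLogLik(un, inst$x)$logLik, got$logLik, tolerance = 1e-10)
    expect_equal(mkLogLik(re, inst$x)$logLik, got$logLik, tolerance = 1e-10)
  }
})

test_that("gamma and invariant mixtures behave as advertised", {
  set.seed(7)
  inst <- randomInstance(6, 30)
  # mixture likelihood equals the brute-force mixture
  mod <- mkModel(gammaShape = 0.5)
  rc <- paeML:::.rateClasses(mod)
  expect_equal(mkLogLik(inst$tree, inst$x, mod)$logLik,
               bruteLogLik(inst$tree, inst$m, rc$rates, rc$weights),
               tolerance = 1e-10)
  modI <- mkModel(gammaShape = 0.5, pInvariant = 0.2)
  rcI <- paeML:::.rateClasses(modI)
  expect_equal(mkLogLik(inst$tree, inst$x, modI)$logLik,
               bruteLogLik(inst$tree, inst$m, rcI$rates, rcI$weights),
               tolerance = 1e-10)
  # alpha -> infinity converges to the homogeneous model
  expect_equal(mkLogLik(inst$tree, inst$x, mkModel(gammaShape = 1e6))$logLik,
               mkLogLik(inst$tree, inst$x)$logLik, tolerance = 1e-6)
  # compiled kernel agrees with the plain-R reference path
  po <- ape::reorder.phylo(inst$tree, "postorder")
  pat <- inst$m[po$tip.label, ]
  expect_equal(paeML:::.siteLikInternal(po, pat, modI),
               paeML:::.siteLikR(po, pat, modI), tolerance = 1e-13)
})

test_that("character additivity: duplication doubles lnL, all-zero adds its own term", {
  set.seed(3)
  inst <- randomInstance(5, 10)
  ll <- mkLogLik(inst$tree, inst$x)$logLik
  x2 <- taxonAreaMatrix(cbind(inst$m, inst$m),
                        species = sprintf("s%d", 1:20))
  expect_equal(mkLogLik(inst$tree, x2)$logLik, 2 * ll, tolerance = 1e-10)
  xz <- taxonAreaMatrix(cbind(inst$m, zero = 0L))
  zll <- mkLogLik(inst$tree,
                  taxonAreaMatrix(matrix(0L, 5, 1,
                    dimnames = list(rownames(inst$m), "z"))))$logLik
  expect_equal(mkLogLik(inst$tree, xz)$logLik, ll + zll, tolerance = 1e-10)
})

test_that("branch-length/shape optimisation improves on its start and is deterministic", {
  set.seed(21)
  tr <- ape::rtree(6); tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.8)
  x <- simulateMatrix(tr, 200, alpha = 0.8, seed = 5)
  f1 <- mkFit(tr, x, gamma = TRUE)
  f2 <- mkFit(tr, x, gamma = TRUE)
  expect_identical(f1$logLik, f2$logLik)           # no randomness
  expect_identical(f1$tree$edge.length, f2$tree$edge.length)
  # at least as good as the likelihood at the initial parsimony lengths
  init <- f1$tree
  pe <- paeML:::.parsimonyEdgeChanges(ape::reorder.phylo(tr, "postorder"),
                                      presence(x))
  init$edge.length <- pmax((pe$changes + 0.5) / 200, 1e-6)
  expect_gte(f1$logLik, mkLogLik(init, x, f1$model)$logLik)
  # fitted alpha within sane bounds
  expect_gte(f1$alpha, 0.02); expect_lte(f1$alpha, 100)
  # +I fit never loses to the nested +G fit
  fI <- mkFit(tr, x, gamma = TRUE, invariant = TRUE)
  expect_gte(fI$logLik, f1$logLik - 1e-6)
})

test_that("an all-constant matrix drives branch lengths to the floor with a warning", {
  tr <- readAreaTree("((A:1,B:1):1,(C:1,D:1):1);")
  x <- taxonAreaMatrix(matrix(0L, 4, 5,
    dimnames = list(c("A", "B", "C", "D"), sprintf("s%d", 1:5))))
  expect_warning(fit <- mkFit(tr, x, gamma = FALSE), "no signal")
  expect_true(all(fit$tree$edge.length <= 1e-5))
})
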