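test_that("endpoint-conditioned paths respect parity, endpoints and degenerate cases", {
  set.seed(4)
  expect_equal(sampleBranchHistory(0, 0, 0, 1),
               data.frame(state = 0, duration = 0))
  expect_error(sampleBranchHistory(0, 1, 0, 1), "impossible path")
  for (i in 1:500) {
    a <- rbinom(1, 1, 0.5); b <- rbinom(1, 1, 0.5)
    t <- runif(1, 0.01, 3); r <- runif(1, 0.2, 3)
    seg <- sampleBranchHistory(a, b, t, r)
    expect_equal(sum(seg$duration), t, tolerance = 1e-12)
    expect_equal(seg$state[1], a)
    expect_equal(seg$state[nrow(seg)], b)
    expect_equal((nrow(seg) - 1) %% 2, as.numeric(a != b))
    if (nrow(seg) > 1) expect_true(all(diff(seg$state) != 0))
  }
})

test_that("conditional change counts match the analytic law on one branch", {
  # P(no change | 0 -> 0, t = 1, r = 1) = e^-1 / ((1 + e^-2)/2)
  set.seed(99)
  n <- 20000
  zero <- mean(replicate(n, nrow(sampleBranchHistory(0, 0, 1, 1)) == 1))
  p <- exp(-1) / (0.5 * (1 + exp(-2)))
  expect_lt(abs(zero - p), 4 * sqrt(p * (1 - p) / n))
  # expected changes per unit length converge to the conditional expectation:
  # E[N | parity even] = lambda * tanh(lambda) at lambda = rt
  lam <- 1.5
  nch <- replicate(n, nrow(sampleBranchHistory(1, 1, lam, 1)) - 1)
  expect_equal(mean(nch), lam * tanh(lam), tolerance = 0.05)
})

test_that("sampled ancestral states reproduce the pruning marginal posterior", {
  set.seed(6)
  tr <- ape::rtree(6); tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
  states <- setNames(rbinom(6, 1, 0.5), tr$tip.label)
  for (r in c(0.5, 1.5)) {
    post <- marginalPosterior(tr, states, r)
    freq <- rowMeans(replicate(8000, sampleAncestralStates(tr, states, r)))
    expect_lt(max(abs(freq - post)), 0.025)
  }
  # two-tip analytic check: internal node posterior for tips (0,0)
  tr2 <- readAreaTree("(A:0.4,B:0.6);")
  st2 <- c(A = 0, B = 0)
  post2 <- marginalPosterior(tr2, st2, 1)
  pr <- function(t, s) if (s == 0) (1 + exp(-2 * t)) / 2 else (1 - exp(-2 * t)) / 2
  manual <- 0.5 * pr(0.4, 1) * pr(0.6, 1) /
    (0.5 * pr(0.4, 1) * pr(0.6, 1) + 0.5 * pr(0.4, 0) * pr(0.6, 0))
  expect_equal(post2[[3]], manual, tolerance = 1e-12)
  set.seed(11)
  freq2 <- mean(replicate(20000, sampleAncestralStates(tr2, st2, 1)[3]))
  expect_lt(abs(freq2 - manual), 3 * sqrt(manual * (1 - manual) / 20000))
})

test_that("full character maps are consistent, tip-faithful and reproducible", {
  set.seed(13)
  tr <- ape::rtree(6); tr$edge.length <- runif(nrow(tr$edge), 0.2, 0.8)
  x <- simulateMatrix(tr, 6, seed = 5)
  ms <- mapCharacter(tr, x, "sp2", mkModel(0.8), nSamples = 400, seed = 21,
                     keepHistories = TRUE)
  col <- presence(x)[, "sp2"]
  po <- ms$tree
  for (h in ms$histories[1:50]) {
    # tip states of every sampled history equal the observed column
    expect_equal(unname(h$nodeStates[seq_len(6)][match(names(col), po$tip.label)]),
                 unname(col))
    # segments partition each branch and chain consistently between nodes
    for (e in seq_len(nrow(po$edge))) {
      seg <- h$segments[[e]]
      expect_equal(sum(seg$duration), po$edge.length[e], tolerance = 1e-9)
      expect_equal(seg$state[1], h$nodeStates[po$edge[e, 1]])
      expect_equal(seg$state[nrow(seg)], h$nodeStates[po$edge[e, 2]])
    }
  }
  # summary reproducibility from the seed
  ms2 <- mapCharacter(tr, x, "sp2", mkModel(0.8), nSamples = 400, seed = 21)
  expect_identical(ms$nodePosterior, ms2$nodePosterior)
  expect_identical(ms$expectedGains, ms2$expectedGains)
  # node posteriors agree with the exact marginals at the map's rate
  post <- marginalPosterior(tr, presence(x)[, "sp2"], ms$rate)
  expect_lt(max(abs(ms$nodePosterior - post)), 0.08)
  # occupancy bounded by branch lengths
  expect_true(all(ms$expectedOccupancy >= 0))
  expect_true(all(ms$expectedOccupancy <= po$edge.length + 1e-12))
  expect_error(mapCharacter(tr, x, "nope"), "unknown species")
})

test_that("a narrow endemic's gains concentrate on its subtending branch", {
  x <- lvvFixture(300, 10, seed = 3)
  tr <- lvvTruthTree()
  sp <- speciesNames(x)[ncol(presence(x))]   # a {ZIB,BK} endemic
  expect_equal(sort(areaNames(x)[presence(x)[, sp] == 1]), c("BK", "ZIB"))
  ms <- mapCharacter(tr, x, sp, mkModel(), nSamples = 400, seed = 2)
  po <- ms$tree
  stem <- which(po$edge[, 2] == ape::getMRCA(po, c("ZIB", "BK")))
  gains <- ms$expectedGains
  # the stem of {ZIB,BK} carries more expected gains than any other branch
  expect_equal(which.max(gains), stem)
})

test_that("MP ancestral state sets match exhaustive minimal labellings", {
  set.seed(17)
  for (i in 1:20) {
    tr <- ape::rtree(5)
    states <- setNames(rbinom(5, 1, 0.5), tr$tip.label)
    got <- mpAncestralStates(tr, states)
    want <- bruteMPSets(tr, states)
    expect_equal(got$length, want$length)
    expect_identical(got$sets, want$sets)
  }
  # textbook ambiguities
  tr2 <- readAreaTree("(A:1,B:1);")
  amb <- mpAncestralStates(tr2, c(A = 0, B = 1))
  expect_equal(amb$sets[[3]], c(0L, 1L))
  # clean synapomorphy: cherry ancestors are fixed, the root (which sits on
  # the single changing edge) is genuinely ambiguous
  tr4 <- readAreaTree("((A,B),(C,D));")
  clean <- mpAncestralStates(tr4, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(clean$length, 1L)
  fixedNodes <- setdiff(seq_along(clean$sets), 5L)   # all but the root
  expect_true(all(lengths(clean$sets[fixedNodes]) == 1))
  expect_equal(clean$sets[[5]], c(0L, 1L))
})
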