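test_that("Sankoff parsimony matches exhaustive enumeration", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  res <- sankoffParsimony(tr, c(a = 1, b = 1, c = 0))
  ref <- bruteSankoff(tr, c(a = 1, b = 1, c = 0))
  expect_equal(res@score, ref$cost)
  expect_equal(res@score, 1)
  expect_equal(unname(nodeStates(res) > 0), unname(ref$occur))

  # uniform tip states need no changes anywhere
  res0 <- sankoffParsimony(tr, c(a = 0, b = 0, c = 0))
  expect_equal(res0@score, 0)
  expect_true(all(nodeStates(res0)[4:5, "0"] == 1))
  expect_true(all(nodeStates(res0)[4:5, "1"] == 0))

  # random instances, asymmetric costs, missing states
  set.seed(71)
  for (i in 1:60) {
    tr <- ape::rtree(6)
    st <- sample(c(0, 1, NA), 6, replace = TRUE,
                 prob = c(0.45, 0.45, 0.1))
    names(st) <- tr$tip.label
    if (all(is.na(st))) st[1] <- 1
    cg <- sample(c(1, 2, 10), 1)
    cl <- sample(c(1, 3), 1)
    res <- sankoffParsimony(tr, st, costGain = cg, costLoss = cl)
    ref <- bruteSankoff(tr, st, costGain = cg, costLoss = cl)
    expect_equal(res@score, ref$cost)
    expect_equal(unname(nodeStates(res) > 0), unname(ref$occur))
  }
})

test_that("gain:loss cost weighting flips the reconstruction as expected", {
  # trait present in three separate tips of a caterpillar: either three
  # independent gains or one ancestral presence plus losses
  tr <- randomCaterpillar(letters[1:6])
  st <- c(a = 1, b = 0, c = 1, d = 0, e = 1, f = 0)
  equal <- sankoffParsimony(tr, st, 1, 1)
  heavyGain <- sankoffParsimony(tr, st, 10, 1)
  refE <- bruteSankoff(tr, st, 1, 1)
  refH <- bruteSankoff(tr, st, 10, 1)
  expect_equal(equal@score, refE$cost)
  expect_equal(heavyGain@score, refH$cost)
  # with costly gains the multi-loss history wins and ancestral nodes
  # carry the trait
  expect_lt(heavyGain@score, 3 * 10)
  root <- ape::Ntip(tr) + 1
  expect_equal(unname(nodeStates(heavyGain)[root, ]), c(0, 1))
})

test_that("Mk pruning equals exhaustive state summation", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(3:4, 1)
    tr <- ape::rtree(n)
    st <- sample(c(0, 1, NA), n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    names(st) <- tr$tip.label
    q01 <- runif(1, 0.05, 3)
    q10 <- runif(1, 0.05, 3)
    expect_equal(mkLogLik(tr, st, q01 = q01, q10 = q10),
                 bruteMkLogLik(tr, st, q01, q10), tolerance = 1e-9)
    pr <- c(q10, q01) / (q01 + q10)
    expect_equal(mkLogLik(tr, st, q01 = q01, q10 = q10,
                          rootPrior = "stationary"),
                 bruteMkLogLik(tr, st, q01, q10, prior = pr),
                 tolerance = 1e-9)
  }
})

test_that("closed-form 2-state transition probabilities are exact", {
  for (r in c(0.1, 1, 5)) {
    for (t in c(0.01, 0.5, 2)) {
      P <- panphylo:::.mkTransProb(r, r, t)
      expect_equal(P[1, 1], (1 + exp(-2 * r * t)) / 2, tolerance = 1e-12)
      expect_equal(P, bruteMkP(r, r, t), tolerance = 1e-10)
    }
  }
  expect_equal(panphylo:::.mkTransProb(0.3, 0.9, 1.7),
               bruteMkP(0.3, 0.9, 1.7), tolerance = 1e-10)
})

test_that("Mk likelihood is invariant to relabeling and zero-length nodes", {
  tr <- ape::read.tree(text = "((a:1,b:2):0.5,(c:0.7,d:0.3):1.2);")
  st <- c(a = 1, b = 0, c = 1, d = NA)
  base <- mkLogLik(tr, st, q01 = 0.4, q10 = 0.8)
  # shuffled state vector, same mapping
  expect_equal(mkLogLik(tr, st[c(3, 1, 4, 2)], q01 = 0.4, q10 = 0.8), base)
  # a zero-length resolution of a multifurcation does not change lnL
  multi <- ape::read.tree(text = "(a:1,b:1,c:1);")
  resolved <- ape::read.tree(text = "((a:1,b:1):0,c:1);")
  st3 <- c(a = 1, b = 0, c = 1)
  expect_equal(mkLogLik(multi, st3, q01 = 0.4, q10 = 0.8),
               mkLogLik(resolved, st3, q01 = 0.4, q10 = 0.8),
               tolerance = 1e-12)
  # a leaf hanging at zero distance from the root contributes its prior
  leaf <- ape::read.tree(text = "(a:0);")
  expect_equal(mkLogLik(leaf, c(a = 1), q01 = 1, q10 = 1), log(0.5))
  expect_error(mkLogLik(tr, st, q01 = -1, q10 = 1))
})

test_that("fitMk recovers rates and respects nesting", {
  tr <- simulateYuleTree(400, 1, seed = 101)
  sim <- simulateBinaryTrait(tr, 0.5, 1.0, seed = 102)
  fit <- fitMk(tr, sim$tipStates)
  expect_gt(fit$model@q01, 0.5 / 2)
  expect_lt(fit$model@q01, 0.5 * 2)
  expect_gt(fit$model@q10, 1.0 / 2)
  expect_lt(fit$model@q10, 1.0 * 2)

  # asymmetric lnL always >= symmetric lnL on the same data
  for (s in 1:5) {
    tr <- simulateYuleTree(40, 1, seed = s)
    sim <- simulateBinaryTrait(tr, 0.8, 0.4, seed = s + 50)
    f1 <- fitMk(tr, sim$tipStates, symmetric = TRUE)
    f2 <- fitMk(tr, sim$tipStates, symmetric = FALSE)
    expect_gte(f2$lnL, f1$lnL - 1e-6)
  }

  # no observed gains drives the gain rate to its lower bound
  tr <- simulateYuleTree(30, 1, seed = 7)
  st <- setNames(rep(0, 30), tr$tip.label)
  f <- fitMk(tr, st)
  expect_lt(f$model@q01, 1.1e-4)
})

test_that("symmetric fits rarely lose more than the chi-squared bound on null data", {
  ok <- 0
  for (s in 1:20) {
    tr <- simulateYuleTree(100, 1, seed = 300 + s)
    sim <- simulateBinaryTrait(tr, 0.5, 0.5, seed = 400 + s)
    cmp <- compareMkModels(tr, sim$tipStates)
    if (cmp$mk2$lnL - cmp$mk1$lnL < 1.92) ok <- ok + 1
  }
  expect_gte(ok, 16)
})

test_that("marginal ancestral states match exhaustive enumeration", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:4, 1)
    tr <- ape::rtree(n)
    st <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    q01 <- runif(1, 0.1, 2)
    q10 <- runif(1, 0.1, 2)
    ours <- nodeStates(mkMarginalStates(tr, st, q01 = q01, q10 = q10))
    ref <- bruteMkMarginals(tr, st, q01, q10)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-9)
    expect_equal(unname(rowSums(ours)), rep(1, nrow(ours)),
                 tolerance = 1e-9)
  }
  # symmetric rates and mirrored tip data give an equivocal root
  cherry <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ms <- mkMarginalStates(cherry, c(a = 1, b = 0, c = 0, d = 1),
                         q01 = 0.7, q10 = 0.7)
  expect_equal(unname(nodeStates(ms)[5, ]), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("likelihood-ratio test reproduces worked examples", {
  lrt <- likelihoodRatioTest(-267696, -249591, df = 2)
  expect_equal(lrt@statistic, 36210)

  lrt2 <- likelihoodRatioTest(0, 11.5 / 2, df = 1)
  expect_equal(lrt2@statistic, 11.5)
  expect_lt(lrt2@p, 0.0007)

  same <- likelihoodRatioTest(-10, -10, df = 1)
  expect_equal(same@statistic, 0)
  expect_equal(same@p, 1)

  expect_warning(neg <- likelihoodRatioTest(-10, -11, df = 1), "negative")
  expect_equal(neg@p, 1)
  expect_equal(neg@statistic, -2)
  expect_error(likelihoodRatioTest(-10, -9, df = 0))
})

test_that("sankoffParsimony reports absent leaves", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  expect_error(sankoffParsimony(tr, c(a = 1, b = 0)), "c")
  expect_error(mkLogLik(tr, c(a = 1, b = 0), q01 = 1, q10 = 1), "c")
})
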