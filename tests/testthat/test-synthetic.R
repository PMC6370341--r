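test_that("Yule trees are ultrametric, sized and reproducible", {
  tr <- simulateYuleTree(2, 1, seed = 1)
  expect_equal(ape::Ntip(tr), 2L)
  d <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(d[1], d[2], tolerance = 1e-9)

  tr10 <- simulateYuleTree(10, 2, seed = 4)
  expect_equal(ape::Ntip(tr10), 10L)
  expect_true(ape::is.ultrametric(tr10, tol = 1e-8))
  expect_identical(ape::write.tree(simulateYuleTree(10, 2, seed = 4)),
                   ape::write.tree(tr10))
  expect_false(identical(ape::write.tree(simulateYuleTree(10, 2, seed = 5)),
                         ape::write.tree(tr10)))
  expect_error(simulateYuleTree(1, 1, seed = 1))
  expect_error(simulateYuleTree(5, 1))  # seed is mandatory
})

test_that("binary trait simulation follows the 2-state Markov process", {
  tr <- simulateYuleTree(50, 1, seed = 2)
  # no gain rate and ancestral absence keeps every tip at 0
  sim <- simulateBinaryTrait(tr, q01 = 0, q10 = 1, rootState = 0, seed = 3)
  expect_true(all(sim$tipStates == 0))
  expect_true(all(sim$nodeStates == 0))

  # tip frequency on a long-branch star tree converges to the
  # stationary distribution q01/(q01+q10)
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:4000, ":50", collapse = ","), ");"))
  simS <- simulateBinaryTrait(star, 0.5, 1.0, seed = 6)
  expect_equal(mean(simS$tipStates), 0.5 / 1.5, tolerance = 0.035)

  sim2 <- simulateBinaryTrait(tr, 0.4, 0.7, seed = 8)
  expect_identical(simulateBinaryTrait(tr, 0.4, 0.7, seed = 8)$tipStates,
                   sim2$tipStates)
  expect_error(simulateBinaryTrait(tr, 0, 0, seed = 1))
})

test_that("partial genome simulation is Bernoulli thinning of present genes", {
  m <- matrix(1L, 2, 2000,
              dimnames = list(c("g1", "g2"), paste0("c", 1:2000)))
  m[2, 1:1000] <- 0L
  tab <- genePresenceTable(m, recovery = 1)

  full <- simulatePartialGenomes(tab, 1.0, seed = 5)
  expect_identical(presenceMatrix(full), presenceMatrix(tab))

  part <- simulatePartialGenomes(tab, 0.8, seed = 5)
  kept <- sum(presenceMatrix(part)[1, ])
  expect_gte(kept, qbinom(5e-4, 2000, 0.8))
  expect_lte(kept, qbinom(1 - 5e-4, 2000, 0.8))
  # absent genes stay absent
  expect_true(all(presenceMatrix(part)[2, 1:1000] == 0))
  expect_equal(unname(recovery(part)), c(0.8, 0.8))

  expect_identical(presenceMatrix(simulatePartialGenomes(tab, 0.8, seed = 5)),
                   presenceMatrix(part))
  expect_error(simulatePartialGenomes(tab, 1.2, seed = 1), "recovery")
  expect_error(simulatePartialGenomes(tab, 0, seed = 1), "recovery")
})

test_that("recombination simulator honours its parameterization", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  pure <- simulateClonalFrameAlignment(tr, theta = 0.02, ROverTheta = 0,
                                       delta = 50, nu = 0.05, L = 5000,
                                       seed = 2)
  expect_equal(sum(pure$events$type == "import"), 0L)
  expect_gt(sum(pure$events$type == "mutation"), 0L)

  # realized import tract lengths have mean ~delta
  sim <- simulateClonalFrameAlignment(tr, theta = 0.02, ROverTheta = 2,
                                      delta = 40, nu = 0.1, L = 50000,
                                      seed = 3)
  imp <- sim$events[sim$events$type == "import", ]
  expect_gt(nrow(imp), 2000)
  se <- sd(imp$length) / sqrt(nrow(imp))
  expect_lt(abs(mean(imp$length) - 40), 5 * se + 1)

  # alignment and log are reproducible and consistent
  sim2 <- simulateClonalFrameAlignment(tr, theta = 0.02, ROverTheta = 2,
                                       delta = 40, nu = 0.1, L = 50000,
                                       seed = 3)
  expect_identical(as.character(sim$alignment), as.character(sim2$alignment))
  expect_identical(sim$events$nSub, sim2$events$nSub)
  expect_true(all(sim$events$pos + sim$events$length - 1 <= 50000))

  expect_error(
    simulateClonalFrameAlignment(tr, 0.01, 1, delta = 0.5, nu = 0.1,
                                 L = 100, seed = 1),
    "delta")
})

test_that("codon simulation respects omega classes and the seed", {
  tr <- simulateYuleTree(6, 1, seed = 11)
  tr$edge.length <- tr$edge.length * 0.4
  # omega = 0: every leaf translates to the same protein
  aln <- simulateCodonAlignment(tr, kappa = 2,
                                siteClasses = list(c(1, 0)),
                                LCodons = 150, seed = 12)
  prots <- as.character(Biostrings::translate(aln))
  expect_equal(length(unique(prots)), 1L)
  ng <- neiGojobori(aln)
  expect_true(any(ng$dS > 0))

  expect_identical(
    as.character(simulateCodonAlignment(tr, 2, list(c(1, 0)),
                                        LCodons = 150, seed = 12)),
    as.character(aln))
  expect_error(
    simulateCodonAlignment(tr, 2, list(c(0.5, 0.1), c(0.4, 1)),
                           LCodons = 10, seed = 1),
    "sum to 1")

  # kappa shifts the transition/transversion balance of realized changes
  two <- ape::read.tree(text = "(a:0.05,b:0.05);")
  alnK <- simulateCodonAlignment(two, kappa = 4, list(c(1, 1)),
                                 LCodons = 30000, seed = 13)
  m <- do.call(rbind, strsplit(as.character(alnK), ""))
  diff <- which(m[1, ] != m[2, ])
  ts <- paste0(pmin(m[1, diff], m[2, diff]), pmax(m[1, diff], m[2, diff]))
  tsn <- sum(ts %in% c("AG", "CT"))
  ratio <- tsn / (length(diff) - tsn)
  # per position a codon has 1 transition and 2 transversion neighbours,
  # so the expected count ratio is ~kappa/2 at small divergence
  expect_gt(ratio, 4 / 2 * 0.75)
  expect_lt(ratio, 4 / 2 * 1.35)
})

test_that("two-population trees implement both segregation regimes", {
  comp <- simulateTwoPopulationTree(9, "complete", seed = 21)
  expect_equal(ape::Ntip(comp$tree), 18L)
  expect_equal(as.vector(sort(table(comp$populations))), c(9L, 9L))
  expect_equal(pTest(comp$tree, comp$populations), 1L)
  expect_equal(unweightedUnifrac(comp$tree, comp$populations), 1)

  none <- simulateTwoPopulationTree(9, "none", seed = 22)
  expect_equal(as.vector(sort(table(none$populations))), c(9L, 9L))
  expect_gt(pTest(none$tree, none$populations), 1L)

  rep1 <- simulateTwoPopulationTree(9, "none", seed = 23)
  rep2 <- simulateTwoPopulationTree(9, "none", seed = 23)
  expect_identical(ape::write.tree(rep1$tree), ape::write.tree(rep2$tree))
  expect_identical(rep1$populations, rep2$populations)
  expect_error(simulateTwoPopulationTree(1, "none", seed = 1))
})
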