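test_that("percent difference equals a position-by-position recount", {
  d <- percentDifference(c(a = "ACGT", b = "ACGA"))
  expect_equal(d["a", "b"], 0.25)
  expect_equal(diag(d), c(a = 0, b = 0))

  d0 <- percentDifference(c(a = "ACGT", b = "ACGT"))
  expect_equal(d0["a", "b"], 0)

  set.seed(12)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", 1:10)
  d <- percentDifference(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(d[i, j], mean(mat[i, ] != mat[j, ]))
      expect_equal(d[i, j], d[j, i])
    }
  }
  expect_true(all(d >= 0 & d <= 1))
})

test_that("gap handling distinguishes onegap and ignore modes", {
  # terminal overhangs are ignored in onegap mode
  aln <- c(a = "--ACGT", b = "TTACGT")
  expect_equal(percentDifference(aln)["a", "b"], 0)
  # an internal gap run counts once against an incremented length
  aln2 <- c(a = "AC--GT", b = "ACTTGT")
  expect_equal(percentDifference(aln2)["a", "b"], 1 / 5)
  expect_equal(percentDifference(aln2, gapMode = "ignore")["a", "b"], 0)
  # two runs, one per sequence
  aln3 <- c(a = "A-CCGT", b = "AGCC-T")
  expect_equal(percentDifference(aln3)["a", "b"], 2 / 6)
  expect_error(percentDifference(c(a = "AA--", b = "--TT")),
               "zero comparable")
})

test_that("representative clustering cuts average linkage at the cutoff", {
  aln <- c(s1 = "AAAA", s2 = "AAAA", s3 = "TTTT")
  cr <- clusterRepresentatives(aln, cutoff = 0.01)
  expect_equal(length(cr$representatives), 2L)
  expect_equal(unname(cr$members[c("s1", "s2")]), c(1, 1))
  expect_equal(cr$representatives[1], "s1")  # lexicographic tie-break

  # all pairs above the cutoff: everyone represents itself
  aln2 <- c(x = "AAAA", y = "AATT", z = "TTTT")
  cr2 <- clusterRepresentatives(aln2, cutoff = 0.01)
  expect_equal(length(cr2$representatives), 3L)

  # clusters equal a brute-force average-linkage cut
  set.seed(3)
  base <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  mut <- function(s, k) {
    pos <- sample(100, k)
    s[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(s, collapse = "")
  }
  seqs <- c(r1 = paste(base, collapse = ""), r2 = mut(base, 1),
            r3 = mut(base, 2), q1 = mut(base, 40), q2 = mut(base, 41))
  cr3 <- clusterRepresentatives(seqs, cutoff = 0.05)
  expect_equal(unname(cr3$members["r1"]), unname(cr3$members["r2"]))
  expect_false(cr3$members[["r1"]] == cr3$members[["q1"]])
})

test_that("population subsampling draws without replacement per population", {
  ids <- c(paste0("h", 1:12), paste0("b", 1:9))
  aln <- setNames(rep("ACGT", 21), ids)
  pops <- setNames(rep(c("HOT", "BATS"), c(12, 9)), ids)
  reps <- subsamplePopulations(aln, pops, nPerPop = 9, nReplicates = 3,
                               seed = 11)
  expect_length(reps, 3L)
  for (r in reps) {
    expect_length(r, 18L)
    expect_equal(sum(startsWith(names(r), "b")), 9L)
    expect_equal(anyDuplicated(names(r)), 0L)
    # a population of exactly nPerPop is always fully included
    expect_setequal(names(r)[startsWith(names(r), "b")], paste0("b", 1:9))
  }
  reps2 <- subsamplePopulations(aln, pops, nPerPop = 9, nReplicates = 3,
                                seed = 11)
  expect_identical(lapply(reps, names), lapply(reps2, names))
  expect_error(subsamplePopulations(aln, pops, nPerPop = 10, seed = 1),
               "BATS")
})

test_that("unweighted UniFrac matches brute-force branch classification", {
  set.seed(21)
  for (i in 1:40) {
    tr <- ape::rtree(10)
    pops <- setNames(sample(rep(c("A", "B"), 5)), tr$tip.label)
    expect_equal(unweightedUnifrac(tr, pops), bruteUnifrac(tr, pops),
                 tolerance = 1e-12)
  }
  # reciprocal monophyly: every branch is unique to one population
  two <- simulateTwoPopulationTree(5, "complete", seed = 3)
  expect_equal(unweightedUnifrac(two$tree, two$populations), 1)
  # a population against itself has no unique branch length
  one <- setNames(rep("A", 10), ape::rtree(10)$tip.label)
  tr1 <- ape::rtree(10)
  expect_equal(unweightedUnifrac(tr1, setNames(rep("A", 10),
                                               tr1$tip.label)), 0)
  # swapping population names changes nothing
  tr <- ape::rtree(8)
  pops <- setNames(rep(c("A", "B"), 4), tr$tip.label)
  swapped <- setNames(ifelse(pops == "A", "B", "A"), names(pops))
  expect_equal(unweightedUnifrac(tr, pops),
               unweightedUnifrac(tr, swapped))
  unrooted <- ape::unroot(ape::rtree(6))
  expect_error(
    unweightedUnifrac(unrooted, setNames(rep(c("A", "B"), 3),
                                         unrooted$tip.label)),
    "midpointRoot")
})

test_that("P-test change counts equal exhaustive Fitch minimization", {
  set.seed(8)
  for (i in 1:15) {
    tr <- ape::rtree(8)
    pops <- setNames(sample(c("A", "B"), 8, replace = TRUE),
                     tr$tip.label)
    if (length(unique(pops)) < 2) pops[1] <- setdiff(c("A", "B"), pops[2])
    expect_equal(pTest(tr, pops), bruteFitch(tr, pops))
  }
  # alternating labels on a caterpillar force one change per cherry pair
  for (n in 3:5) {
    tr <- randomCaterpillar(paste0("t", seq_len(2 * n)))
    pops <- setNames(rep(c("A", "B"), n), tr$tip.label)
    expect_equal(pTest(tr, pops), n)
  }
  # reciprocal monophyly needs exactly one change
  two <- simulateTwoPopulationTree(4, "complete", seed = 5)
  expect_equal(pTest(two$tree, two$populations), 1L)
  # a single population needs none
  tr <- ape::rtree(6)
  expect_equal(pTest(tr, setNames(rep("A", 6), tr$tip.label)), 0L)
  # invariance to rerooting
  tr <- ape::rtree(10)
  pops <- setNames(sample(rep(c("A", "B"), 5)), tr$tip.label)
  ref <- pTest(tr, pops)
  for (node in 12:15) {
    rerooted <- ape::root(tr, node = node, resolve.root = TRUE)
    expect_equal(pTest(rerooted, pops), ref)
  }
})

test_that("permutation significance detects segregation and is never zero", {
  two <- simulateTwoPopulationTree(9, "complete", seed = 42)
  res <- permutationSignificance(two$tree, two$populations, "unifrac",
                                 nIters = 1000, seed = 1)
  expect_lte(res@p, 0.01)
  expect_gt(res@p, 0)
  resP <- permutationSignificance(two$tree, two$populations, "ptest",
                                  nIters = 1000, seed = 1)
  expect_lte(resP@p, 0.01)

  # reproducible for a fixed seed
  res2 <- permutationSignificance(two$tree, two$populations, "unifrac",
                                  nIters = 200, seed = 9)
  res3 <- permutationSignificance(two$tree, two$populations, "unifrac",
                                  nIters = 200, seed = 9)
  expect_equal(res2@p, res3@p)

  expect_error(
    permutationSignificance(two$tree, two$populations, "unifrac",
                            nIters = 0, seed = 1),
    "nIters")
})
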