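# Pairwise sequence distances, representative clustering, population
# subsampling, and the two phylogenetic population-divergence tests
# (unweighted UniFrac, parsimony P-test) with permutation significance.

.alnToMatrix <- function(aln) {
  if (inherits(aln, "XStringSet")) {
    seqs <- as.character(aln)
  } else if (is.character(aln)) {
    seqs <- aln
  } else {
    stop("alignment must be a DNAStringSet or named character vector")
  }
  if (is.null(names(seqs))) stop("alignment sequences must be named")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("ragged alignment")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

# one pair, mothur-style "onegap": terminal gap overhangs ignored, an
# internal contiguous gap run in either sequence counts as one difference
# and one compared position
.pairDistOnegap <- function(a, b) {
  gapA <- a == "-"
  gapB <- b == "-"
  both <- which(!gapA & !gapB)
  if (length(both) == 0L) {
    stop("sequence pair has zero comparable columns")
  }
  span <- both[1L]:both[length(both)]
  a <- a[span]; b <- b[span]
  gapA <- gapA[span]; gapB <- gapB[span]
  keep <- !(gapA & gapB)            # columns gapped in both are skipped
  a <- a[keep]; b <- b[keep]
  gapA <- gapA[keep]; gapB <- gapB[keep]
  base <- !gapA & !gapB
  diffs <- sum(a[base] != b[base])
  len <- sum(base)
  for (g in list(gapA, gapB)) {
    if (any(g)) {
      r <- rle(g)
      runs <- sum(r$values)         # each maximal gap run: one difference
      diffs <- diffs + runs
      len <- len + runs
    }
  }
  diffs / len
}

.pairDistIgnore <- function(a, b) {
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("sequence pair has zero comparable columns")
  sum(a[keep] != b[keep]) / sum(keep)
}

#' Pairwise percent-difference matrix for an alignment
#'
#' Proportion of differing positions for every sequence pair.  The default
#' gap handling mirrors mothur's \code{dist.seqs} "onegap" behavior: a
#' contiguous gap run in either sequence counts as a single difference,
#' and terminal gap overhangs are ignored.  Mode "ignore" drops every
#' column where either sequence has a gap.
#'
#' @param aln a \code{DNAStringSet} or named character vector of
#'   equal-length gapped sequences (>= 2).
#' @param gapMode "onegap" (default) or "ignore".
#' @return A symmetric numeric matrix with zero diagonal, values in
#'   [0, 1]; attribute \code{gapMode} records the setting used.
#' @examples
#' percentDifference(c(a = "ACGT", b = "ACGA"))  # 0.25 off-diagonal
#' @export
percentDifference <- function(aln, gapMode = c("onegap", "ignore")) {
  gapMode <- match.arg(gapMode)
  m <- .alnToMatrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  pairFun <- if (gapMode == "onegap") .pairDistOnegap else .pairDistIgnore
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pairFun(m[i, ], m[j, ])
    }
  }
  attr(d, "gapMode") <- gapMode
  d
}

#' Representative sequences by average-linkage clustering at a cutoff
#'
#' Clusters sequences by average linkage on the percent-difference matrix,
#' cuts the dendrogram at \code{cutoff}, and picks as representative of
#' each cluster the member with the minimum summed within-cluster distance
#' (ties broken by lexicographically first id).
#'
#' @inheritParams percentDifference
#' @param cutoff distance cutoff (default 0.01).
#' @return A list with \code{members} (named cluster index per sequence)
#'   and \code{representatives} (character vector, one id per cluster).
#' @export
clusterRepresentatives <- function(aln, cutoff = 0.01,
                                   gapMode = c("onegap", "ignore")) {
  d <- percentDifference(aln, match.arg(gapMode))
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, h = cutoff)
  reps <- vapply(sort(unique(cl)), function(g) {
    ids <- sort(names(cl)[cl == g])
    if (length(ids) == 1L) return(ids)
    tot <- rowSums(d[ids, ids, drop = FALSE])
    ids[which.min(tot)]   # which.min takes the first (lexicographic) tie
  }, character(1))
  list(members = cl, representatives = reps)
}

#' Subsample equal numbers of sequences per population
#'
#' Draws \code{nPerPop} sequences without replacement from each
#' population, independently for each replicate (replicates are
#' independent draws, not a partition).
#'
#' @param aln a \code{DNAStringSet} or named character vector.
#' @param populations named character vector mapping sequence id to
#'   population label.
#' @param nPerPop sequences drawn per population (default 9).
#' @param nReplicates independent replicate draws (default 3).
#' @param seed RNG seed (required).
#' @return A list of \code{nReplicates} subsampled alignments, each with
#'   \code{nPerPop} sequences per population.
#' @export
subsamplePopulations <- function(aln, populations, nPerPop = 9,
                                 nReplicates = 3, seed) {
  if (inherits(aln, "XStringSet")) {
    ids <- names(aln)
  } else {
    ids <- names(aln)
  }
  populations <- populations[names(populations) %in% ids]
  pops <- split(names(populations), populations)
  short <- names(pops)[lengths(pops) < nPerPop]
  if (length(short)) {
    stop("population(s) with fewer than ", nPerPop, " sequences: ",
         paste(short, collapse = ", "))
  }
  .withSeed(seed, {
    lapply(seq_len(nReplicates), function(r) {
      chosen <- unlist(lapply(pops, function(p) sample(p, nPerPop)),
                       use.names = FALSE)
      aln[chosen]
    })
  })
}

# per-edge population content (1 = only pop A below, 2 = only B, 3 = both,
# 0 = no mapped leaves below); used by UniFrac and its permutations
.edgeLeafSets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(tree$edge[, 2L], function(nd) below[[nd]])
}

.unifracFromLabels <- function(edgeSets, edgeLen, lab) {
  # lab: integer 1/2 per tip index, NA for unmapped
  uniq <- 0
  tot <- 0
  for (i in seq_along(edgeSets)) {
    l <- lab[edgeSets[[i]]]
    l <- l[!is.na(l)]
    if (length(l) == 0L) next
    tot <- tot + edgeLen[i]
    if (length(unique(l)) == 1L) uniq <- uniq + edgeLen[i]
  }
  if (tot == 0) stop("no mapped leaves on the tree")
  uniq / tot
}

#' Unweighted UniFrac distance between two populations on a tree
#'
#' The fraction of branch length leading exclusively to leaves of a single
#' population, out of the total branch length subtending mapped leaves.
#'
#' @param tree rooted ape \code{phylo} (use [midpointRoot()] first if
#'   unrooted).
#' @param populations named character vector mapping every leaf to one of
#'   exactly two population labels.
#' @return The UniFrac statistic, in [0, 1].
#' @export
unweightedUnifrac <- function(tree, populations) {
  .checkTree(tree)
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted: apply midpointRoot() first")
  }
  lv <- unique(unname(populations[tree$tip.label]))
  if (length(lv) == 1L && !anyNA(lv)) return(0)  # community vs itself
  lab <- .popLabels(tree, populations)
  .unifracFromLabels(.edgeLeafSets(tree), tree$edge.length, lab)
}

.popLabels <- function(tree, populations) {
  miss <- setdiff(tree$tip.label, names(populations))
  if (length(miss)) {
    stop("leaves without population label: ", paste(miss, collapse = ", "))
  }
  lv <- sort(unique(unname(populations[tree$tip.label])))
  if (length(lv) != 2L) {
    stop("exactly 2 populations required (got ", length(lv), ")")
  }
  match(populations[tree$tip.label], lv)
}

# Fitch/Sankoff unit-cost change count over k labels
.fitchChanges <- function(tree, lab) {
  k <- max(lab)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  S <- matrix(Inf, nnode, k)
  S[cbind(seq_len(ntip), lab)] <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]
    ch <- edge[i, 2L]
    childCost <- pmin(S[ch, ], min(S[ch, ]) + 1)  # stay, or switch for 1
    if (all(!is.finite(S[p, ]))) S[p, ] <- 0
    S[p, ] <- S[p, ] + childCost
  }
  min(S[ntip + 1L, ])
}

#' Parsimony P-test statistic: minimum population-label changes
#'
#' Fitch parsimony count of the minimum number of population-label
#' changes required to explain the observed labels on the tree, treating
#' the label as an unordered character.  The count is invariant to
#' rerooting.
#'
#' @inheritParams unweightedUnifrac
#' @return Integer-valued change count (>= 0; 1 means the populations are
#'   reciprocally monophyletic, 0 a single population).
#' @export
pTest <- function(tree, populations) {
  .checkTree(tree)
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted: apply midpointRoot() first")
  }
  miss <- setdiff(tree$tip.label, names(populations))
  if (length(miss)) {
    stop("leaves without population label: ", paste(miss, collapse = ", "))
  }
  lab <- match(populations[tree$tip.label],
               sort(unique(unname(populations[tree$tip.label]))))
  if (max(lab) == 1L) return(0L)
  as.integer(.fitchChanges(tree, lab))
}

#' Permutation significance for UniFrac or the P-test
#'
#' Permutes the leaf-to-population assignment (preserving group sizes) and
#' reports \eqn{p = (\#\{permutations\ at\ least\ as\ extreme\} + 1) /
#' (n_{iters} + 1)}, which is never exactly zero.  "At least as extreme"
#' means >= the observed UniFrac (larger = more divergence) and <= the
#' observed change count for the P-test (fewer changes = more structure).
#'
#' @inheritParams unweightedUnifrac
#' @param statistic "unifrac" or "ptest".
#' @param nIters number of permutations (default 1000; must be >= 1).
#' @param seed RNG seed (required).
#' @return A [DivergenceTestResult-class].
#' @export
permutationSignificance <- function(tree, populations,
                                    statistic = c("unifrac", "ptest"),
                                    nIters = 1000, seed) {
  statistic <- match.arg(statistic)
  if (nIters < 1) stop("nIters must be >= 1")
  .checkTree(tree)
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted: apply midpointRoot() first")
  }
  lab <- .popLabels(tree, populations)
  edgeSets <- .edgeLeafSets(tree)
  elen <- tree$edge.length
  statFun <- if (statistic == "unifrac") {
    function(l) .unifracFromLabels(edgeSets, elen, l)
  } else {
    function(l) .fitchChanges(tree, l)
  }
  obs <- statFun(lab)
  exceed <- .withSeed(seed, {
    sum(vapply(seq_len(nIters), function(i) {
      perm <- sample(lab)
      s <- statFun(perm)
      if (statistic == "unifrac") s >= obs - 1e-12 else s <= obs + 1e-12
    }, logical(1)))
  })
  new("DivergenceTestResult", statistic = statistic, observed = obs,
      p = (exceed + 1) / (nIters + 1), nIters = as.integer(nIters),
      seed = as.integer(seed))
}
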