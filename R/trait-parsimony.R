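# Weighted (Sankoff) parsimony for a binary trait.  The cost of a 0->1
# change (trait gain) and of a 1->0 change (trait loss) can differ, which
# is how "gains weighted 10x higher than losses" analyses are expressed.

#' Ancestral reconstruction of a binary trait by weighted parsimony
#'
#' Sankoff dynamic programming over a rooted tree with an asymmetric
#' binary cost matrix.  Transitions are counted per branch irrespective of
#' branch length.  All states attaining the minimum total cost at a node
#' (over all most-parsimonious reconstructions, MPRs) are reported, so
#' downstream summaries see ambiguity explicitly rather than an arbitrary
#' tie-break.  Tips with missing states contribute zero cost for either
#' state (they are not dropped).
#'
#' @param tree rooted ape \code{phylo}.
#' @param states named vector of tip states (0, 1 or NA), containing every
#'   tree leaf.
#' @param costGain cost of a 0 -> 1 change (> 0).
#' @param costLoss cost of a 1 -> 0 change (> 0).
#' @return An [AncestralReconstruction-class] with \code{method}
#'   "parsimony": \code{states} is an indicator matrix of MPR membership
#'   per node and \code{score} the minimum total weighted cost.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
#' sankoffParsimony(tr, c(a = 1, b = 1, c = 0))
#' @export
sankoffParsimony <- function(tree, states, costGain = 1, costLoss = 1) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (!is.finite(costGain) || !is.finite(costLoss) ||
      costGain <= 0 || costLoss <= 0) {
    stop("costs must be finite and positive")
  }
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(states))
  if (length(missing_tips)) {
    stop("leaves absent from character matrix: ",
         paste(missing_tips, collapse = ", "))
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  # cost[from, to]
  cost <- matrix(c(0, costLoss, costGain, 0), 2L, 2L)

  S <- matrix(Inf, nnode, 2L)
  for (i in seq_len(ntip)) {
    s <- states[[tips[i]]]
    if (is.na(s)) {
      S[i, ] <- c(0, 0)
    } else if (s == 0) {
      S[i, ] <- c(0, Inf)
    } else if (s == 1) {
      S[i, ] <- c(Inf, 0)
    } else {
      stop("tip state must be 0, 1 or NA (tip '", tips[i], "')")
    }
  }

  kids <- .childList(tree)
  post <- .postorderNodes(tree)
  # branch contribution of child c seen from parent state k
  branchMin <- function(child, k) {
    min(cost[k, 1L] + S[child, 1L], cost[k, 2L] + S[child, 2L])
  }
  for (n in post) {
    for (k in 1:2) {
      S[n, k] <- sum(vapply(kids[[n]], branchMin, numeric(1), k = k))
    }
  }
  total <- min(S[root, ])

  # up-pass: U[n, k] = min cost of the rest of the tree given node n in
  # state k; a state is in some MPR iff S + U attains the global minimum
  U <- matrix(Inf, nnode, 2L)
  U[root, ] <- 0
  pre <- rev(post)
  for (p in pre) {
    ch <- kids[[p]]
    sibSum <- vapply(1:2, function(k)
      sum(vapply(ch, branchMin, numeric(1), k = k)), numeric(1))
    for (child in ch) {
      for (j in 1:2) {
        U[child, j] <- min(vapply(1:2, function(k) {
          U[p, k] + cost[k, j] + sibSum[k] - branchMin(child, k)
        }, numeric(1)))
      }
    }
  }
  mpr <- (S + U) <= total + 1e-9
  mode(mpr) <- "numeric"
  colnames(mpr) <- c("0", "1")
  rownames(mpr) <- c(tips, paste0("node", (ntip + 1L):nnode))
  new("AncestralReconstruction", method = "parsimony", states = mpr,
      score = total, tree = tree)
}
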