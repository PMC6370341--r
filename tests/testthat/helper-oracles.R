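# Independent brute-force oracles used to check the dynamic-programming
# and pruning implementations.  These enumerate over all internal
# assignments / subsets and must stay independent of the package's own
# algorithms.

# exhaustive weighted parsimony: minimum cost over all assignments of
# internal nodes (and free assignment of missing tips)
bruteSankoff <- function(tree, states, costGain = 1, costLoss = 1) {
  cost <- matrix(c(0, costLoss, costGain, 0), 2, 2)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  freeTips <- which(is.na(states[tree$tip.label]))
  freeNodes <- c(internal, freeTips)
  fixed <- integer(nnode)
  fixed[seq_len(ntip)] <- states[tree$tip.label]
  best <- Inf
  occur <- matrix(FALSE, nnode, 2)
  grid <- expand.grid(rep(list(0:1), length(freeNodes)))
  for (r in seq_len(nrow(grid))) {
    asg <- fixed
    asg[freeNodes] <- as.integer(grid[r, ])
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tot <- tot + cost[asg[tree$edge[e, 1]] + 1, asg[tree$edge[e, 2]] + 1]
    }
    if (tot < best - 1e-9) {
      best <- tot
      occur[] <- FALSE
    }
    if (tot <= best + 1e-9) {
      occur[cbind(seq_len(nnode), asg + 1)] <-
        occur[cbind(seq_len(nnode), asg + 1)] | TRUE
    }
  }
  list(cost = best, occur = occur)
}

# exhaustive Mk likelihood by summing over all internal (and missing-tip)
# state assignments, using the package's closed-form P only through an
# independent reimplementation
bruteMkP <- function(q01, q10, t) {
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  # series expansion via eigen (independent of the closed form)
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

bruteMkLogLik <- function(tree, states, q01, q10,
                          prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  freeTips <- which(is.na(states[tree$tip.label]))
  freeNodes <- c(internal, freeTips)
  fixed <- integer(nnode)
  fixed[seq_len(ntip)] <- states[tree$tip.label]
  grid <- expand.grid(rep(list(0:1), length(freeNodes)))
  Pm <- lapply(seq_len(nrow(tree$edge)),
               function(e) bruteMkP(q01, q10, tree$edge.length[e]))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    asg <- fixed
    asg[freeNodes] <- as.integer(grid[r, ])
    lik <- prior[asg[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      lik <- lik * Pm[[e]][asg[tree$edge[e, 1]] + 1, asg[tree$edge[e, 2]] + 1]
    }
    tot <- tot + lik
  }
  log(tot)
}

# exhaustive marginal state probabilities per node
bruteMkMarginals <- function(tree, states, q01, q10, prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  fixed <- integer(nnode)
  fixed[seq_len(ntip)] <- states[tree$tip.label]
  grid <- expand.grid(rep(list(0:1), length(internal)))
  Pm <- lapply(seq_len(nrow(tree$edge)),
               function(e) bruteMkP(q01, q10, tree$edge.length[e]))
  marg <- matrix(0, nnode, 2)
  for (r in seq_len(nrow(grid))) {
    asg <- fixed
    asg[internal] <- as.integer(grid[r, ])
    lik <- prior[asg[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      lik <- lik * Pm[[e]][asg[tree$edge[e, 1]] + 1, asg[tree$edge[e, 2]] + 1]
    }
    marg[cbind(seq_len(nnode), asg + 1)] <-
      marg[cbind(seq_len(nnode), asg + 1)] + lik
  }
  marg / rowSums(marg)
}

# exhaustive Fitch count: minimum label changes over all internal
# assignments
bruteFitch <- function(tree, labels) {
  labs <- sort(unique(unname(labels[tree$tip.label])))
  k <- length(labs)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  fixed <- match(labels[tree$tip.label], labs)
  grid <- expand.grid(rep(list(seq_len(k)), length(internal)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    asg <- c(fixed, as.integer(grid[r, ]))
    ch <- sum(asg[tree$edge[, 1]] != asg[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# branch-classification UniFrac oracle using phangorn descendants
bruteUnifrac <- function(tree, populations) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  uniq <- tot <- 0
  for (i in seq_along(desc)) {
    pops <- unique(unname(populations[tree$tip.label[desc[[i]]]]))
    if (length(pops) == 0) next
    tot <- tot + tree$edge.length[i]
    if (length(pops) == 1) uniq <- uniq + tree$edge.length[i]
  }
  uniq / tot
}

# naive average-linkage agglomeration returning merge heights, computed
# as the mean of all original cross-cluster distances (UPGMA definition)
bruteAverageLinkageHeights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# exact hypergeometric upper/lower tails by subset enumeration
bruteHyperTails <- function(k, K, N, n) {
  idx <- seq_len(N)
  marked <- idx <= K
  subs <- utils::combn(N, n)
  draws <- colSums(matrix(marked[subs], nrow = n))
  c(over = mean(draws >= k), under = mean(draws <= k))
}

randomCaterpillar <- function(labels) {
  txt <- paste0(labels[1], ":1,", labels[2], ":1")
  for (i in 3:length(labels)) {
    txt <- paste0("(", txt, "):1,", labels[i], ":1")
  }
  ape::read.tree(text = paste0("(", txt, ");"))
}
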