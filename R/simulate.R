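# Synthetic-data generators with the statistical structure the analyses
# assume: Yule trees, binary traits under an asymmetric 2-rate Markov
# process, partial single-cell assemblies (Bernoulli gene retention),
# ClonalFrame-style recombinant sequence evolution, GY94 codon
# alignments, and two-population labelled trees.  Every generator is a
# pure function of (inputs, seed).

#' Simulate a Yule (pure-birth) tree
#'
#' @param nTaxa number of leaves (>= 2).
#' @param birthRate speciation rate (> 0).
#' @param seed RNG seed (required).
#' @return An ultrametric rooted ape \code{phylo}.
#' @export
simulateYuleTree <- function(nTaxa, birthRate = 1, seed) {
  if (nTaxa < 2) stop("nTaxa must be >= 2")
  if (birthRate <= 0) stop("birthRate must be > 0")
  .withSeed(seed, {
    tr <- ape::rphylo(nTaxa, birth = birthRate, death = 0)
    tr$tip.label <- paste0("t", seq_len(nTaxa))
    tr
  })
}

# one CTMC draw along a branch: returns end state (0/1)
.evolveBinary <- function(state, q01, q10, t) {
  P <- .mkTransProb(q01, q10, t)
  sample.int(2L, 1L, prob = P[state + 1L, ]) - 1L
}

#' Simulate a binary trait along a tree
#'
#' Continuous-time 2-state Markov evolution (gain rate \code{q01}, loss
#' rate \code{q10}) along each branch, using the exact transition
#' probabilities.  The true internal node states are returned alongside
#' the tip states so ancestral-state methods can be scored against the
#' truth.
#'
#' @param tree ape \code{phylo} with branch lengths.
#' @param q01,q10 gain and loss rates (>= 0, not both 0 when the root
#'   state is drawn from the stationary distribution).
#' @param rootState 0, 1 or "stationary" (draw from q01/(q01+q10)).
#' @param seed RNG seed (required).
#' @return A list with \code{tipStates} (named 0/1 vector) and
#'   \code{nodeStates} (0/1 vector over all nodes in ape numbering).
#' @export
simulateBinaryTrait <- function(tree, q01, q10, rootState = "stationary",
                                seed) {
  .checkTree(tree)
  if (q01 < 0 || q10 < 0) stop("rates must be non-negative")
  if (identical(rootState, "stationary") && q01 + q10 == 0) {
    stop("stationary root state undefined when both rates are zero")
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  .withSeed(seed, {
    states <- integer(nnode)
    states[root] <- if (identical(rootState, "stationary")) {
      as.integer(runif(1) < q01 / (q01 + q10))
    } else {
      as.integer(rootState)
    }
    pre <- ape::reorder.phylo(tree, "postorder")
    for (i in rev(seq_len(nrow(pre$edge)))) {
      p <- pre$edge[i, 1L]
      ch <- pre$edge[i, 2L]
      states[ch] <- .evolveBinary(states[p], q01, q10, pre$edge.length[i])
    }
    list(tipStates = setNames(states[seq_len(ntip)], tree$tip.label),
         nodeStates = states)
  })
}

#' Simulate partial genome assemblies by Bernoulli gene retention
#'
#' Emulates partial single-cell assemblies: each gene present in the full
#' genome is retained independently with probability equal to that
#' genome's recovery fraction; absent genes stay absent.  The recovery
#' fractions are recorded in the output table.
#'
#' @param table full-genome [GenePresenceTable-class].
#' @param recoveryFractions per-genome retention probability in (0, 1]
#'   (recycled if scalar).
#' @param seed RNG seed (required).
#' @return A [GenePresenceTable-class] of the partial assemblies.
#' @export
simulatePartialGenomes <- function(table, recoveryFractions, seed) {
  m <- presenceMatrix(table)
  if (length(recoveryFractions) == 1L) {
    recoveryFractions <- rep(recoveryFractions, nrow(m))
  }
  if (any(recoveryFractions <= 0 | recoveryFractions > 1)) {
    stop("recovery fractions must lie in (0, 1]")
  }
  .withSeed(seed, {
    out <- m
    for (i in seq_len(nrow(m))) {
      pres <- which(m[i, ] == 1L)
      keep <- runif(length(pres)) <= recoveryFractions[i]
      out[i, pres[!keep]] <- 0L
    }
    genePresenceTable(out, recovery = recoveryFractions,
                      marker = table@marker)
  })
}

.NT <- c("A", "C", "G", "T")
# kappa-weighted move away from the current base (1..4 = A,C,G,T)
.mutateBase <- function(cur, kappa) {
  # transitions: A<->G (1,3), C<->T (2,4)
  w <- rep(1, 4L)
  w[cur] <- 0
  ti <- c(3L, 4L, 1L, 2L)[cur]
  w[ti] <- kappa
  sample.int(4L, 1L, prob = w)
}

#' Forward simulation of mutation and homologous recombination
#'
#' Evolves a sequence of length \code{L} along a tree.  On each branch of
#' length \code{t}, point mutations arrive as a Poisson process with rate
#' \code{theta} per site (Jukes-Cantor moves; transitions weighted by
#' \code{kappa} when supplied) and import initiations with rate
#' \code{(R/theta) * theta} per site.  Each import covers a
#' geometric-length tract with mean \code{delta} (truncated at the
#' sequence end; sequences are linear), whose sites are independently
#' substituted with probability \code{nu}.  Events on a branch are
#' applied in time order, so overlapping imports are permitted and the
#' last event at a site wins.  The event log records every mutation and
#' every import with its tract and substituted-site count.
#'
#' @param tree ape \code{phylo} with branch lengths (time units).
#' @param theta per-site mutation rate.
#' @param ROverTheta import initiation rate relative to mutation.
#' @param delta mean import tract length, bp (>= 1).
#' @param nu per-site divergence of imported DNA, in [0, 0.75].
#' @param L sequence length (>= 1).
#' @param seed RNG seed (required).
#' @param kappa transition/transversion weight (default 1 = Jukes-Cantor).
#' @return A list with \code{alignment} (leaf sequences as a
#'   \code{DNAStringSet}) and \code{events} (data.frame: branch, type,
#'   time, pos, length, nSub).
#' @export
simulateClonalFrameAlignment <- function(tree, theta, ROverTheta, delta,
                                         nu, L, seed, kappa = 1) {
  .checkTree(tree)
  if (L < 1) stop("L must be >= 1")
  if (delta < 1) stop("delta must be >= 1")
  if (nu < 0 || nu > 0.75) stop("nu must lie in [0, 0.75]")
  if (theta < 0 || ROverTheta < 0) stop("rates must be non-negative")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  .withSeed(seed, {
    seqs <- vector("list", nnode)
    seqs[[root]] <- sample.int(4L, L, replace = TRUE)
    logs <- list()
    po <- ape::reorder.phylo(tree, "postorder")
    edges <- rev(seq_len(nrow(po$edge)))  # preorder: parents before kids
    for (i in edges) {
      p <- po$edge[i, 1L]
      ch <- po$edge[i, 2L]
      t <- po$edge.length[i]
      s <- seqs[[p]]
      nMut <- rpois(1L, theta * t * L)
      nImp <- rpois(1L, ROverTheta * theta * t * L)
      nEv <- nMut + nImp
      if (nEv) {
        evType <- rep(c(1L, 2L), c(nMut, nImp))  # 1 mutation, 2 import
        evTime <- runif(nEv, 0, t)
        ord <- order(evTime)
        evType <- evType[ord]
        evTime <- evTime[ord]
        evPos <- integer(nEv)
        evLen <- integer(nEv)
        evSub <- integer(nEv)
        for (r in seq_len(nEv)) {
          if (evType[r] == 1L) {
            pos <- sample.int(L, 1L)
            s[pos] <- .mutateBase(s[pos], kappa)
            evPos[r] <- pos
            evLen[r] <- 1L
            evSub[r] <- 1L
          } else {
            start <- sample.int(L, 1L)
            len <- min(rgeom(1L, 1 / delta) + 1L, L - start + 1L)
            tract <- start:(start + len - 1L)
            hit <- tract[runif(len) < nu]
            for (pos in hit) s[pos] <- .mutateBase(s[pos], kappa)
            evPos[r] <- start
            evLen[r] <- len
            evSub[r] <- length(hit)
          }
        }
        logs[[length(logs) + 1L]] <- data.frame(
          branch = ch, type = c("mutation", "import")[evType],
          time = evTime, pos = evPos, length = evLen, nSub = evSub)
      }
      seqs[[ch]] <- s
    }
    tipSeqs <- vapply(seq_len(ntip), function(i)
      paste(.NT[seqs[[i]]], collapse = ""), character(1))
    names(tipSeqs) <- tree$tip.label
    events <- if (length(logs)) do.call(rbind, logs) else
      data.frame(branch = integer(0), type = character(0),
                 time = numeric(0), pos = integer(0), length = integer(0),
                 nSub = integer(0))
    list(alignment = Biostrings::DNAStringSet(tipSeqs), events = events)
  })
}

#' Simulate a codon alignment under a GY94 site-class mixture
#'
#' Each codon site draws an omega class from \code{siteClasses}, then
#' evolves down the tree under the corresponding GY94 generator.  Stop
#' codons are never emitted (they are not part of the state space).
#'
#' @param tree ape \code{phylo}, branch lengths in expected substitutions
#'   per codon.
#' @param kappa transition/transversion ratio.
#' @param siteClasses matrix-like with columns (proportion, omega), or a
#'   list of 2-vectors; proportions must sum to 1 within 1e-9.
#' @param codonFreqs "uniform" or a 61-vector over [senseCodons()].
#' @param LCodons number of codon sites (>= 1).
#' @param seed RNG seed (required).
#' @return A \code{DNAStringSet} of leaf sequences (3 x LCodons nt);
#'   attribute \code{siteClass} gives each site's true class index.
#' @export
simulateCodonAlignment <- function(tree, kappa, siteClasses,
                                   codonFreqs = "uniform", LCodons, seed) {
  .checkTree(tree)
  if (LCodons < 1) stop("LCodons must be >= 1")
  if (is.list(siteClasses)) siteClasses <- do.call(rbind, siteClasses)
  siteClasses <- as.matrix(siteClasses)
  props <- siteClasses[, 1L]
  omegas <- siteClasses[, 2L]
  if (abs(sum(props) - 1) > 1e-9) {
    stop("site class proportions must sum to 1")
  }
  ce <- .codonSetup()
  pi <- if (identical(codonFreqs, "uniform")) rep(1 / 61, 61) else {
    if (abs(sum(codonFreqs) - 1) > 1e-6) stop("codonFreqs must sum to 1")
    as.numeric(codonFreqs)
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  egs <- lapply(omegas, function(w) {
    Q <- gy94RateMatrix(kappa, w, pi)
    eg <- .gy94Eigen(Q)
    eg$pi <- attr(Q, "pi")
    eg
  })
  .withSeed(seed, {
    cls <- sample.int(length(props), LCodons, replace = TRUE, prob = props)
    states <- matrix(0L, nnode, LCodons)
    states[root, ] <- sample.int(61L, LCodons, replace = TRUE, prob = pi)
    po <- ape::reorder.phylo(tree, "postorder")
    for (i in rev(seq_len(nrow(po$edge)))) {
      p <- po$edge[i, 1L]
      ch <- po$edge[i, 2L]
      t <- po$edge.length[i]
      for (k in seq_along(props)) {
        sites <- which(cls == k)
        if (!length(sites)) next
        P <- .pmatFromEigen(egs[[k]], t)
        P <- P / rowSums(P)
        for (from in unique(states[p, sites])) {
          idx <- sites[states[p, sites] == from]
          states[ch, idx] <- sample.int(61L, length(idx), replace = TRUE,
                                        prob = P[from, ])
        }
      }
    }
    tipSeqs <- vapply(seq_len(ntip), function(i)
      paste(ce$codons[states[i, ]], collapse = ""), character(1))
    names(tipSeqs) <- tree$tip.label
    out <- Biostrings::DNAStringSet(tipSeqs)
    attr(out, "siteClass") <- cls
    out
  })
}

#' Simulate a two-population labelled tree
#'
#' "complete" segregation joins two independent Yule clades (each scaled
#' to unit height) at a root, giving reciprocal monophyly; "none" draws a
#' single Yule tree and assigns population labels by random interleaving.
#'
#' @param nPerPop leaves per population (>= 2).
#' @param segregation "none" or "complete".
#' @param seed RNG seed (required).
#' @param birthRate Yule speciation rate.
#' @return A list with \code{tree} (rooted \code{phylo}) and
#'   \code{populations} (named character vector, labels "A" and "B").
#' @export
simulateTwoPopulationTree <- function(nPerPop,
                                      segregation = c("none", "complete"),
                                      seed, birthRate = 1) {
  segregation <- match.arg(segregation)
  if (nPerPop < 2) stop("nPerPop must be >= 2")
  .withSeed(seed, {
    if (segregation == "complete") {
      mk <- function(tag) {
        tr <- ape::rphylo(nPerPop, birth = birthRate, death = 0)
        tr$tip.label <- paste0(tag, seq_len(nPerPop))
        depth <- max(ape::node.depth.edgelength(tr))
        tr$edge.length <- tr$edge.length / depth
        tr
      }
      a <- mk("A")
      b <- mk("B")
      tree <- ape::read.tree(text = paste0(
        "(", sub(";$", "", ape::write.tree(a)), ":0.5,",
        sub(";$", "", ape::write.tree(b)), ":0.5);"))
      pops <- setNames(rep(c("A", "B"), each = nPerPop), tree$tip.label)
      pops[] <- ifelse(startsWith(names(pops), "A"), "A", "B")
    } else {
      tree <- ape::rphylo(2L * nPerPop, birth = birthRate, death = 0)
      tree$tip.label <- paste0("t", seq_len(2L * nPerPop))
      lab <- sample(rep(c("A", "B"), each = nPerPop))
      pops <- setNames(lab, tree$tip.label)
    }
    list(tree = tree, populations = pops)
  })
}
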