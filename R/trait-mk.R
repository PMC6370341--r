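# Mk-model machinery for a binary trait: exact 2x2 transition
# probabilities, Felsenstein pruning, ML rate estimation, marginal
# ancestral states and the MK1-vs-Mk2 likelihood-ratio comparison.

# closed-form P(t) for the 2-state chain with gain rate q01, loss rate q10
.mkTransProb <- function(q01, q10, t) {
  s <- q01 + q10
  if (s == 0) return(diag(2))
  p1 <- q01 / s  # stationary frequency of state 1
  e <- exp(-s * t)
  matrix(c(1 - p1 * (1 - e), p1 * (1 - e),
           (1 - p1) * (1 - e), 1 - (1 - p1) * (1 - e)),
         2L, 2L, byrow = TRUE)
}

# tip partial likelihoods: missing tips get (1, 1)
.mkTipPartials <- function(tree, states) {
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(states))
  if (length(missing_tips)) {
    stop("leaves absent from character matrix: ",
         paste(missing_tips, collapse = ", "))
  }
  L <- matrix(1, ape::Ntip(tree) + tree$Nnode, 2L)
  for (i in seq_along(tips)) {
    s <- states[[tips[i]]]
    if (!is.na(s)) {
      if (!s %in% c(0, 1)) stop("tip state must be 0, 1 or NA")
      L[i, ] <- if (s == 0) c(1, 0) else c(0, 1)
    }
  }
  L
}

.mkRootPrior <- function(rootPrior, q01, q10) {
  rootPrior <- match.arg(rootPrior, c("equal", "stationary"))
  if (rootPrior == "equal") return(c(0.5, 0.5))
  s <- q01 + q10
  if (s == 0) stop("stationary root prior undefined when both rates are 0")
  c(q10, q01) / s
}

# pruning with per-edge scaling over a precomputed postorder edge table;
# scalar closed-form transition probabilities keep the inner loop
# allocation-free (this is the hot path of fitMk)
.mkPruneFast <- function(edge, elen, root, L, q01, q10) {
  s <- q01 + q10
  l0 <- L[, 1L]
  l1 <- L[, 2L]
  logScale <- 0
  if (s == 0) {
    f <- rep(1, length(elen))
  } else {
    f <- 1 - exp(-s * elen)
  }
  p1 <- if (s == 0) 0.5 else q01 / s
  for (i in seq_along(elen)) {
    ch <- edge[i, 2L]
    par <- edge[i, 1L]
    a <- l0[ch]
    b <- l1[ch]
    fi <- if (s == 0) 0 else f[i]
    c0 <- a + p1 * fi * (b - a)
    c1 <- b + (1 - p1) * fi * (a - b)
    m <- if (c0 > c1) c0 else c1
    if (m <= 0) return(list(root = c(0, 0), logScale = -Inf))
    logScale <- logScale + log(m)
    l0[par] <- l0[par] * (c0 / m)
    l1[par] <- l1[par] * (c1 / m)
  }
  list(root = c(l0[root], l1[root]), logScale = logScale)
}

.mkPrune <- function(tree, L, q01, q10) {
  po <- ape::reorder.phylo(tree, "postorder")
  .mkPruneFast(po$edge, po$edge.length, ape::Ntip(tree) + 1L, L, q01, q10)
}

#' Log-likelihood of a binary trait under the Mk model
#'
#' Felsenstein pruning with exact closed-form 2x2 transition probabilities
#' \eqn{P(t) = \exp(Qt)}.  Tips with missing states carry flat partial
#' likelihoods (1, 1).
#'
#' @param tree rooted ape \code{phylo} with branch lengths.
#' @param states named vector of tip states (0, 1 or NA).
#' @param model an [MkModel-class] (or supply \code{q01}, \code{q10}).
#' @param q01,q10 gain and loss rates, used when \code{model} is missing.
#' @param rootPrior "equal" (uniform over the two states, default) or
#'   "stationary" (the chain's stationary distribution).
#' @return The log-likelihood (numeric scalar).
#' @export
mkLogLik <- function(tree, states, model = NULL, q01 = NULL, q10 = NULL,
                     rootPrior = c("equal", "stationary")) {
  .checkTree(tree)
  if (!is.null(model)) {
    q01 <- model@q01
    q10 <- model@q10
  }
  if (q01 < 0 || q10 < 0) stop("rates must be non-negative")
  if (q01 == 0 && q10 == 0) stop("rates must not both be zero")
  prior <- .mkRootPrior(match.arg(rootPrior), q01, q10)
  L <- .mkTipPartials(tree, states)
  pr <- .mkPrune(tree, L, q01, q10)
  lik <- sum(prior * pr$root)
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logScale
}

#' Maximum-likelihood fit of the Mk model
#'
#' Rates are estimated by bounded optimization in log-rate space.  The
#' search starts from a 5 x 5 grid of rate pairs log-spaced over
#' [1e-4, 1e3] (5 values on the diagonal for the symmetric model); the
#' best grid points seed L-BFGS-B refinements and the returned optimum is
#' never worse than any grid point.  Deterministic for a fixed grid.
#'
#' @inheritParams mkLogLik
#' @param symmetric fit the one-parameter MK1 model (q01 = q10) instead of
#'   the asymmetric two-parameter Mk2 model.
#' @param bounds rate search interval (per unit branch length).
#' @return A list with elements \code{model} (the fitted
#'   [MkModel-class]), \code{lnL}, and \code{rootPrior}.
#' @export
fitMk <- function(tree, states, symmetric = FALSE,
                  rootPrior = c("equal", "stationary"),
                  bounds = c(1e-4, 1e3)) {
  rootPrior <- match.arg(rootPrior)
  .checkTree(tree)
  L0 <- .mkTipPartials(tree, states)
  po <- ape::reorder.phylo(tree, "postorder")
  root <- ape::Ntip(tree) + 1L
  prior_fun <- function(q01, q10) .mkRootPrior(rootPrior, q01, q10)

  negll <- function(par) {
    q01 <- exp(par[1L])
    q10 <- if (symmetric) q01 else exp(par[2L])
    pr <- .mkPruneFast(po$edge, po$edge.length, root, L0, q01, q10)
    lik <- sum(prior_fun(q01, q10) * pr$root)
    if (lik <= 0 || !is.finite(pr$logScale)) return(1e10)
    -(log(lik) + pr$logScale)
  }

  g <- log(exp(seq(log(bounds[1L]), log(bounds[2L]), length.out = 5L)))
  starts <- if (symmetric) matrix(g, ncol = 1L) else
    as.matrix(expand.grid(g, g))
  gridVal <- apply(starts, 1L, negll)
  ord <- order(gridVal)
  best <- list(value = gridVal[ord[1L]], par = starts[ord[1L], ])
  lo <- rep(log(bounds[1L]), ncol(starts))
  hi <- rep(log(bounds[2L]), ncol(starts))
  for (k in head(ord, 3L)) {
    fit <- tryCatch(
      optim(starts[k, ], negll, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("Mk optimization failed from every start; grid values: ",
         paste(signif(-gridVal, 4), collapse = ", "))
  }
  q01 <- unname(exp(best$par[1L]))
  q10 <- if (symmetric) q01 else unname(exp(best$par[2L]))
  list(model = mkModel(q01, q10, symmetric = symmetric), lnL = -best$value,
       rootPrior = rootPrior)
}

#' Marginal ancestral state probabilities under the Mk model
#'
#' Standard up-down (inside-outside) pass: for each node the marginal
#' posterior of its state given all tip data, under the supplied rates and
#' root prior.  Probabilities sum to 1 per node.
#'
#' @inheritParams mkLogLik
#' @return An [AncestralReconstruction-class] with \code{method} "ml";
#'   \code{states} holds the marginal probabilities and \code{score} the
#'   log-likelihood.
#' @export
mkMarginalStates <- function(tree, states, model = NULL, q01 = NULL,
                             q10 = NULL,
                             rootPrior = c("equal", "stationary")) {
  .checkTree(tree)
  if (!is.null(model)) {
    q01 <- model@q01
    q10 <- model@q10
  }
  prior <- .mkRootPrior(match.arg(rootPrior), q01, q10)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  Ltip <- .mkTipPartials(tree, states)

  # unscaled down-pass partials per node (fine for moderate trees; the
  # scaled version in mkLogLik is used for the returned log-likelihood)
  kids <- .childList(tree)
  pe <- .parentEdge(tree)
  D <- Ltip
  post <- .postorderNodes(tree)
  Pmat <- lapply(seq_len(nrow(tree$edge)),
                 function(i) .mkTransProb(q01, q10, tree$edge.length[i]))
  scale_log <- rep(0, nnode)  # per-node accumulated log scaling
  for (n in post) {
    acc <- 0
    for (ch in kids[[n]]) {
      D[n, ] <- D[n, ] * as.vector(Pmat[[pe[ch]]] %*% D[ch, ])
      acc <- acc + scale_log[ch]
    }
    m <- max(D[n, ])
    D[n, ] <- D[n, ] / m
    scale_log[n] <- acc + log(m)
  }

  # up-pass messages: U[n, ] summarizes the tree outside the clade of n
  U <- matrix(0, nnode, 2L)
  U[root, ] <- prior
  for (p in rev(post)) {
    for (ch in kids[[p]]) {
      sib <- setdiff(kids[[p]], ch)
      msg <- U[p, ]
      for (s in sib) {
        msg <- msg * as.vector(Pmat[[pe[s]]] %*% D[s, ])
      }
      U[ch, ] <- as.vector(t(Pmat[[pe[ch]]]) %*% msg)
      m <- max(U[ch, ])
      if (m > 0) U[ch, ] <- U[ch, ] / m
    }
  }
  marg <- D * U
  marg <- marg / rowSums(marg)
  colnames(marg) <- c("0", "1")
  rownames(marg) <- c(tree$tip.label, paste0("node", (ntip + 1L):nnode))
  lnL <- mkLogLik(tree, states, q01 = q01, q10 = q10,
                  rootPrior = match.arg(rootPrior))
  new("AncestralReconstruction", method = "ml", states = marg, score = lnL,
      tree = tree)
}

#' Likelihood-ratio test against a chi-squared reference
#'
#' @param lnLNull,lnLAlt log-likelihoods of the nested and general model.
#' @param df degrees of freedom (>= 1).
#' @return An [LrtResult-class].  The statistic is \eqn{2(lnL_{alt} -
#'   lnL_{null})} and is reported even when negative (with a warning, and
#'   p = 1), which flags an optimizer that failed to respect nesting.
#' @examples
#' likelihoodRatioTest(-267696, -249591, df = 2)  # statistic 36210
#' @export
likelihoodRatioTest <- function(lnLNull, lnLAlt, df) {
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (lnLAlt - lnLNull)
  if (stat < 0) {
    warning("negative LRT statistic: alternative fit worse than null")
    p <- 1
  } else {
    p <- pchisq(stat, df = df, lower.tail = FALSE)
  }
  new("LrtResult", lnLNull = lnLNull, lnLAlt = lnLAlt, statistic = stat,
      df = df, p = p)
}

#' Compare symmetric MK1 against asymmetric Mk2
#'
#' Fits both models by maximum likelihood and performs the 1-df
#' likelihood-ratio test justifying (or not) separate gain and loss rates.
#'
#' @inheritParams fitMk
#' @return A list with \code{mk1}, \code{mk2} (fits as returned by
#'   [fitMk()]) and \code{lrt} (an [LrtResult-class]).
#' @export
compareMkModels <- function(tree, states,
                            rootPrior = c("equal", "stationary")) {
  rootPrior <- match.arg(rootPrior)
  mk1 <- fitMk(tree, states, symmetric = TRUE, rootPrior = rootPrior)
  mk2 <- fitMk(tree, states, symmetric = FALSE, rootPrior = rootPrior)
  if (mk2$lnL < mk1$lnL) {
    # the symmetric optimum is a valid asymmetric point; never report a
    # nesting violation caused by the optimizer
    mk2 <- list(model = mkModel(mk1$model@q01, mk1$model@q10,
                                symmetric = FALSE),
                lnL = mk1$lnL, rootPrior = rootPrior)
  }
  list(mk1 = mk1, mk2 = mk2,
       lrt = likelihoodRatioTest(mk1$lnL, mk2$lnL, df = 1))
}
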