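# Goldman-Yang (GY94) codon substitution machinery: the 61-state rate
# matrix, F3x4 equilibrium frequencies, and the pruning likelihood for
# single-omega, site-class mixture and branch-site models.  Universal
# genetic code only.

.codonEnv <- new.env(parent = emptyenv())

.codonSetup <- function() {
  if (!is.null(.codonEnv$codons)) return(invisible(.codonEnv))
  nt <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  all64 <- paste0(g$p1, g$p2, g$p3)
  gc <- Biostrings::GENETIC_CODE[all64]
  sense <- all64[gc != "*"]
  aa <- gc[gc != "*"]
  n <- length(sense)  # 61
  letters3 <- do.call(rbind, strsplit(sense, ""))
  diffPos <- matrix(0L, n, n)
  isTs <- matrix(FALSE, n, n)
  isSyn <- matrix(FALSE, n, n)
  ts_pairs <- c("AG", "GA", "CT", "TC")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- which(letters3[i, ] != letters3[j, ])
      if (length(d) == 1L) {
        diffPos[i, j] <- diffPos[j, i] <- d
        ts <- paste0(letters3[i, d], letters3[j, d]) %in% ts_pairs
        isTs[i, j] <- isTs[j, i] <- ts
        sy <- aa[i] == aa[j]
        isSyn[i, j] <- isSyn[j, i] <- sy
      }
    }
  }
  .codonEnv$codons <- sense
  .codonEnv$aa <- aa
  .codonEnv$stops <- all64[gc == "*"]
  .codonEnv$letters <- letters3
  .codonEnv$single <- diffPos > 0L
  .codonEnv$isTs <- isTs
  .codonEnv$isSyn <- isSyn
  invisible(.codonEnv)
}

#' The 61 sense codons of the universal genetic code
#' @return Character vector of length 61 (T/C/A/G alphabet, TTT first).
#' @export
senseCodons <- function() .codonSetup()$codons

#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies are estimated from the three
#' codon positions of the alignment (gaps and ambiguous characters
#' excluded), multiplied per codon, the stop-codon mass removed, and the
#' result renormalized over the 61 sense codons.
#'
#' @param aln codon alignment (\code{DNAStringSet} or named character
#'   vector); length divisible by 3, no in-frame stop codons.
#' @return Named numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4Frequencies <- function(aln) {
  ce <- .codonSetup()
  m <- .alnToMatrix(aln)
  if (ncol(m) %% 3L != 0L) stop("alignment length not divisible by 3")
  .checkStops(m)
  freqs <- matrix(0, 3L, 4L, dimnames = list(NULL, c("T", "C", "A", "G")))
  for (pos in 1:3) {
    cols <- seq(pos, ncol(m), by = 3L)
    chars <- m[, cols]
    chars <- chars[chars %in% c("T", "C", "A", "G")]
    tb <- table(factor(chars, levels = c("T", "C", "A", "G")))
    freqs[pos, ] <- as.numeric(tb) / sum(tb)
  }
  pi <- freqs[1L, ce$letters[, 1L]] * freqs[2L, ce$letters[, 2L]] *
    freqs[3L, ce$letters[, 3L]]
  pi <- pi / sum(pi)
  names(pi) <- ce$codons
  pi
}

.checkStops <- function(m) {
  ce <- .codonSetup()
  for (i in seq_len(nrow(m))) {
    cods <- apply(matrix(m[i, ], nrow = 3L), 2L, paste, collapse = "")
    hit <- which(cods %in% ce$stops)
    if (length(hit)) {
      stop("in-frame stop codon in sequence '", rownames(m)[i],
           "' at codon ", hit[1L])
    }
  }
  invisible(m)
}

#' GY94 codon rate matrix
#'
#' Instantaneous rates are zero for multi-nucleotide changes and
#' proportional to \eqn{\pi_j} (synonymous transversion),
#' \eqn{\kappa\pi_j} (synonymous transition), \eqn{\omega\pi_j}
#' (nonsynonymous transversion) and \eqn{\kappa\omega\pi_j}
#' (nonsynonymous transition).  Rows sum to zero and the matrix is scaled
#' so the mean substitution rate at equilibrium is 1 (branch lengths are
#' then expected substitutions per codon).  Zero entries of \eqn{\pi} are
#' floored at 1e-10 (and renormalized) so the chain stays irreducible.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS (>= 0).
#' @param pi codon frequencies over [senseCodons()] (default uniform).
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
gy94RateMatrix <- function(kappa, omega, pi = NULL) {
  ce <- .codonSetup()
  n <- length(ce$codons)
  if (is.null(pi)) pi <- rep(1 / n, n)
  if (kappa <= 0 || omega < 0) stop("need kappa > 0 and omega >= 0")
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1")
  if (any(pi <= 0)) {
    pi <- pmax(pi, 1e-10)
    pi <- pi / sum(pi)
  }
  Q <- matrix(0, n, n, dimnames = list(ce$codons, ce$codons))
  Q[ce$single] <- rep(pi, each = n)[ce$single]
  Q[ce$single & ce$isTs] <- Q[ce$single & ce$isTs] * kappa
  Q[ce$single & !ce$isSyn] <- Q[ce$single & !ce$isSyn] * omega
  diag(Q) <- -rowSums(Q)
  sc <- -sum(pi * diag(Q))
  if (sc > 0) Q <- Q / sc
  attr(Q, "pi") <- pi
  Q
}

# spectral decomposition of a reversible Q (uses the pi it was built with)
.gy94Eigen <- function(Q) {
  pi <- attr(Q, "pi")
  sq <- sqrt(pi)
  B <- (sq * Q) %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = (1 / sq) * e$vectors, Uinv = t(e$vectors) %*% diag(sq),
       values = e$values)
}

.pmatFromEigen <- function(eg, t) {
  P <- eg$U %*% (exp(eg$values * t) * eg$Uinv)
  P[P < 0] <- 0
  P
}

#' Codon models
#'
#' \code{codonModel} describes a single-omega GY94 model (M0);
#' \code{siteClassModel} a mixture of omega classes shared by all
#' branches; \code{branchSiteModel} the branch-site model A with site
#' classes 0, 1, 2a, 2b and a foreground omega that applies only on
#' designated branches (H0 of the branch-site test fixes the foreground
#' omega at 1).
#'
#' @param kappa transition/transversion ratio (> 0).
#' @param omega dN/dS for the single class.
#' @param pi codon frequencies (default uniform over the 61 sense codons).
#' @return An S4 model object accepted by [codonLogLik()].
#' @export
codonModel <- function(kappa, omega, pi = NULL) {
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  new("CodonModel", kappa = kappa, omega = omega, pi = unname(pi))
}

#' @rdname codonModel
#' @export
setClass("CodonModel",
  representation(kappa = "numeric", omega = "numeric", pi = "numeric"))

#' @rdname codonModel
#' @param proportions class proportions (must sum to 1 within 1e-9).
#' @param omegas one dN/dS per class.
#' @export
siteClassModel <- function(kappa, proportions, omegas, pi = NULL) {
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  new("SiteClassModel", kappa = kappa, proportions = unname(proportions),
      omegas = unname(omegas), pi = unname(pi))
}

#' @rdname codonModel
#' @export
setClass("SiteClassModel",
  representation(kappa = "numeric", proportions = "numeric",
                 omegas = "numeric", pi = "numeric"))

setValidity("SiteClassModel", function(object) {
  if (length(object@proportions) != length(object@omegas))
    return("one omega per class required")
  if (abs(sum(object@proportions) - 1) > 1e-9)
    return("class proportions must sum to 1")
  if (any(object@proportions < 0) || any(object@omegas < 0))
    return("proportions and omegas must be non-negative")
  TRUE
})

#' @rdname codonModel
#' @param omega0 purifying-class dN/dS (0 <= omega0 <= 1).
#' @param omega2 foreground dN/dS of classes 2a/2b (>= 1; exactly 1 under
#'   H0).
#' @param foreground integer indices into \code{tree$edge} rows marking
#'   foreground branches (see [stemEdge()]).
#' @export
branchSiteModel <- function(kappa, proportions, omega0, omega2, foreground,
                            pi = NULL) {
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  new("BranchSiteModel", kappa = kappa, proportions = unname(proportions),
      omega0 = omega0, omega2 = omega2,
      foreground = as.integer(foreground), pi = unname(pi))
}

#' @rdname codonModel
#' @export
setClass("BranchSiteModel",
  representation(kappa = "numeric", proportions = "numeric",
                 omega0 = "numeric", omega2 = "numeric",
                 foreground = "integer", pi = "numeric"))

setValidity("BranchSiteModel", function(object) {
  if (length(object@proportions) != 4L)
    return("branch-site model A has exactly 4 site classes (0, 1, 2a, 2b)")
  if (abs(sum(object@proportions) - 1) > 1e-9)
    return("class proportions must sum to 1")
  TRUE
})

# normalize any codon model to a list of classes:
# list(prop, omegaBg, omegaFg)
.modelClasses <- function(model) {
  if (is(model, "CodonModel")) {
    list(list(prop = 1, bg = model@omega, fg = model@omega))
  } else if (is(model, "SiteClassModel")) {
    lapply(seq_along(model@proportions), function(i)
      list(prop = model@proportions[i], bg = model@omegas[i],
           fg = model@omegas[i]))
  } else if (is(model, "BranchSiteModel")) {
    w0 <- model@omega0
    w2 <- model@omega2
    p <- model@proportions
    list(list(prop = p[1], bg = w0, fg = w0),
         list(prop = p[2], bg = 1, fg = 1),
         list(prop = p[3], bg = w0, fg = w2),
         list(prop = p[4], bg = 1, fg = w2))
  } else {
    stop("unsupported model class: ", class(model))
  }
}

# tip partial likelihood matrices (61 x n_patterns) and pattern weights
.codonTipPartials <- function(tree, aln) {
  ce <- .codonSetup()
  m <- .alnToMatrix(aln)
  miss <- setdiff(tree$tip.label, rownames(m))
  if (length(miss)) {
    stop("alignment is missing leaf sequences: ",
         paste(miss, collapse = ", "))
  }
  m <- m[tree$tip.label, , drop = FALSE]
  if (ncol(m) %% 3L != 0L) stop("alignment length not divisible by 3")
  nsite <- ncol(m) %/% 3L
  ntax <- nrow(m)
  codv <- matrix("", ntax, nsite)
  for (i in seq_len(ntax)) {
    codv[i, ] <- apply(matrix(m[i, ], nrow = 3L), 2L, paste, collapse = "")
  }
  pat <- apply(codv, 2L, paste, collapse = "\r")
  upat <- unique(pat)
  widx <- match(pat, upat)
  weights <- tabulate(widx, nbins = length(upat))
  cols <- match(upat, pat)
  # partial per taxon: exact codon -> indicator; anything else (gap,
  # ambiguity, partial codon) -> compatible-codon indicator per position
  tipPart <- vector("list", ntax)
  n61 <- length(ce$codons)
  for (i in seq_len(ntax)) {
    Pm <- matrix(0, n61, length(upat))
    for (s in seq_along(upat)) {
      cod <- codv[i, cols[s]]
      idx <- match(cod, ce$codons)
      if (!is.na(idx)) {
        Pm[idx, s] <- 1
      } else if (cod %in% ce$stops) {
        stop("in-frame stop codon in sequence '", rownames(m)[i], "'")
      } else {
        ok <- rep(TRUE, n61)
        ch <- strsplit(cod, "")[[1L]]
        for (p in 1:3) {
          if (ch[p] %in% c("T", "C", "A", "G")) {
            ok <- ok & ce$letters[, p] == ch[p]
          }
        }
        if (!any(ok)) ok <- rep(TRUE, n61)
        Pm[ok, s] <- 1
      }
    }
    tipPart[[i]] <- Pm
  }
  list(tipPart = tipPart, weights = weights, npat = length(upat))
}

# pruning for one omega class; returns per-pattern log-likelihood
.pruneClass <- function(tree, tipPart, pi, egBg, egFg, foreground, scale) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  npat <- ncol(tipPart[[1L]])
  part <- vector("list", nnode)
  part[seq_len(ntip)] <- tipPart
  logsc <- rep(0, npat)
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length * scale
  eidx <- match(paste(po$edge[, 1L], po$edge[, 2L]),
                paste(tree$edge[, 1L], tree$edge[, 2L]))
  n61 <- nrow(tipPart[[1L]])
  for (i in seq_len(nrow(edge))) {
    eg <- if (eidx[i] %in% foreground) egFg else egBg
    P <- .pmatFromEigen(eg, elen[i])
    contrib <- P %*% part[[edge[i, 2L]]]
    # any positive per-column factor works for scaling; column sums are
    # much cheaper than column maxima
    cm <- .colSums(contrib, n61, npat)
    if (any(cm <= 0)) return(rep(-Inf, npat))
    contrib <- contrib * rep(1 / cm, each = n61)
    logsc <- logsc + log(cm)
    p <- edge[i, 1L]
    part[[p]] <- if (is.null(part[[p]])) contrib else part[[p]] * contrib
  }
  root <- part[[ntip + 1L]]
  lik <- as.vector(crossprod(root, attr(egBg, "pi")))
  ifelse(lik > 0, log(lik) + logsc, -Inf)
}

# cached spectral decomposition: within one fit, gradient perturbations of
# the proportion parameters reuse every class's decomposition
.eigenCached <- function(kappa, omega, pi, cache) {
  if (is.null(cache)) {
    Q <- gy94RateMatrix(kappa, omega, pi)
    eg <- .gy94Eigen(Q)
    attr(eg, "pi") <- attr(Q, "pi")
    return(eg)
  }
  # flush when kappa moves so the cache stays small (one entry per omega)
  if (!identical(cache$kappa, kappa)) {
    cache$kappa <- kappa
    cache$tbl <- list()
  }
  key <- sprintf("%.17g", omega)
  eg <- cache$tbl[[key]]
  if (is.null(eg)) {
    Q <- gy94RateMatrix(kappa, omega, pi)
    eg <- .gy94Eigen(Q)
    attr(eg, "pi") <- attr(Q, "pi")
    cache$tbl[[key]] <- eg
  }
  eg
}

# core likelihood over prepared tip partials
.codonLogLikCore <- function(tree, prep, kappa, classes, pi, scale = 1,
                             foreground = integer(0), cache = NULL) {
  props <- vapply(classes, `[[`, numeric(1), "prop")
  active <- which(props > 0)
  if (!length(active)) stop("all class proportions are zero")
  siteLogs <- matrix(-Inf, length(classes), prep$npat)
  for (k in active) {
    egBg <- .eigenCached(kappa, classes[[k]]$bg, pi, cache)
    egFg <- if (length(foreground) && classes[[k]]$fg != classes[[k]]$bg) {
      .eigenCached(kappa, classes[[k]]$fg, pi, cache)
    } else {
      egBg
    }
    siteLogs[k, ] <- .pruneClass(tree, prep$tipPart, pi, egBg, egFg,
                                 foreground, scale)
  }
  mx <- apply(siteLogs[active, , drop = FALSE], 2L, max)
  if (any(!is.finite(mx))) return(-Inf)
  inner <- colSums(props[active] *
                     exp(sweep(siteLogs[active, , drop = FALSE], 2L, mx)))
  sum(prep$weights * (log(inner) + mx))
}

#' Log-likelihood of a codon alignment under a GY94-family model
#'
#' Per-site Felsenstein pruning over the 61 sense codons with per-site
#' scaling (mandatory, so long alignments do not underflow).  Site-class
#' mixtures sum class-conditional site likelihoods weighted by the class
#' proportions; branch-site models switch the rate matrix on foreground
#' branches per class.  Codons containing gaps or ambiguity codes
#' contribute a partial likelihood of 1 over every compatible codon (they
#' are marginalized, not dropped).
#'
#' @param tree rooted or unrooted ape \code{phylo} with branch lengths in
#'   expected substitutions per codon.
#' @param aln codon alignment containing every tree leaf.
#' @param model a [codonModel()], [siteClassModel()] or
#'   [branchSiteModel()].
#' @param scale global branch-length multiplier (default 1); see
#'   [fitSiteModels()] for why this exists.
#' @return Log-likelihood (numeric scalar).
#' @export
codonLogLik <- function(tree, aln, model, scale = 1) {
  .checkTree(tree)
  prep <- .codonTipPartials(tree, aln)
  fg <- if (is(model, "BranchSiteModel")) model@foreground else integer(0)
  .codonLogLikCore(tree, prep, model@kappa, .modelClasses(model),
                   model@pi, scale = scale, foreground = fg)
}

#' Edge index of the stem branch of a clade
#'
#' Convenience for marking a foreground branch: returns the row of
#' \code{tree$edge} whose child is the most recent common ancestor of
#' \code{tips} (or the tip itself for a single label).
#'
#' @param tree ape \code{phylo}.
#' @param tips character vector of tip labels.
#' @return Integer edge index.
#' @export
stemEdge <- function(tree, tips) {
  node <- if (length(tips) == 1L) {
    match(tips, tree$tip.label)
  } else {
    ape::getMRCA(tree, tips)
  }
  which(tree$edge[, 2L] == node)
}

# K equal-probability beta categories represented by their conditional
# means (the codeml convention for M7/M8)
.betaCategoryMeans <- function(p, q, K) {
  brk <- qbeta(seq(0, 1, length.out = K + 1L), p, q)
  upper <- pbeta(brk[-1L], p + 1, q)
  lower <- pbeta(brk[-(K + 1L)], p + 1, q)
  mu <- (upper - lower) * K * p / (p + q)
  pmin(pmax(mu, 0), 1)
}
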