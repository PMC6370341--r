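# ML fitting of the codon site models (M0, M1a, M2a, M7, M8) and of
# branch-site model A, plus the NG86 counting estimator used as a
# sanity-check oracle for the ML omega estimates.

.logit <- function(p) log(p / (1 - p))
.invlogit <- function(x) 1 / (1 + exp(-x))

# generic multi-start BFGS wrapper on an unconstrained parameterization;
# candidates are (par, value) pairs that must never be beaten downward
.mlMaximize <- function(negll, starts, extraCandidates = list()) {
  best <- NULL
  for (s in starts) {
    v0 <- tryCatch(negll(s), error = function(e) Inf)
    if (is.finite(v0) && (is.null(best) || v0 < best$value)) {
      best <- list(par = s, value = v0)
    }
    fit <- tryCatch(
      optim(s, negll, method = "BFGS",
            control = list(reltol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("codon model optimization failed from every start")
  best
}

# classes builder per site model from the unconstrained parameter vector;
# returns list(classes, report) where report is the natural-scale params
.siteModelSpec <- function(model, K) {
  switch(model,
    M0 = list(
      npar = 1L,
      start = function(w) log(max(w, 1e-3)),
      classes = function(th) {
        w <- exp(th[1L])
        list(classes = list(list(prop = 1, bg = w, fg = w)),
             report = c(omega = w))
      }),
    M1a = list(
      npar = 2L,
      start = function(w) c(.logit(0.8), .logit(min(max(w, 1e-3), 0.9))),
      classes = function(th) {
        p0 <- .invlogit(th[1L])
        w0 <- .invlogit(th[2L])
        list(classes = list(list(prop = p0, bg = w0, fg = w0),
                            list(prop = 1 - p0, bg = 1, fg = 1)),
             report = c(p0 = p0, omega0 = w0))
      }),
    M2a = list(
      npar = 4L,
      start = function(w) c(.logit(0.8), .logit(0.5),
                            .logit(min(max(w, 1e-3), 0.9)), log(1)),
      classes = function(th) {
        p0 <- .invlogit(th[1L])
        p1 <- (1 - p0) * .invlogit(th[2L])
        p2 <- 1 - p0 - p1
        w0 <- .invlogit(th[3L])
        w2 <- 1 + exp(th[4L])
        list(classes = list(list(prop = p0, bg = w0, fg = w0),
                            list(prop = p1, bg = 1, fg = 1),
                            list(prop = p2, bg = w2, fg = w2)),
             report = c(p0 = p0, p1 = p1, p2 = p2, omega0 = w0,
                        omega2 = w2))
      }),
    M7 = list(
      npar = 2L,
      start = function(w) c(log(0.5), log(2)),
      classes = function(th) {
        p <- exp(th[1L])
        q <- exp(th[2L])
        mu <- .betaCategoryMeans(p, q, K)
        list(classes = lapply(mu, function(w)
               list(prop = 1 / K, bg = w, fg = w)),
             report = c(p = p, q = q))
      }),
    M8 = list(
      npar = 4L,
      start = function(w) c(log(0.5), log(2), .logit(0.9), log(1)),
      classes = function(th) {
        p <- exp(th[1L])
        q <- exp(th[2L])
        p0 <- .invlogit(th[3L])
        ws <- 1 + exp(th[4L])
        mu <- .betaCategoryMeans(p, q, K)
        cl <- lapply(mu, function(w) list(prop = p0 / K, bg = w, fg = w))
        cl[[K + 1L]] <- list(prop = 1 - p0, bg = ws, fg = ws)
        list(classes = cl,
             report = c(p = p, q = q, p0 = p0, omegaS = ws))
      }),
    stop("unknown site model: ", model))
}

#' Fit GY94 site models by maximum likelihood
#'
#' Fits any subset of M0 (one omega), M1a (nearly neutral), M2a (positive
#' selection), M7 (beta) and M8 (beta + omega_s > 1) to a codon alignment
#' on a fixed tree.  Branch lengths are taken as given and held fixed; a
#' single global rate multiplier is estimated by default to absorb the
#' difference between nucleotide-unit and codon-unit branch lengths.
#' kappa is estimated jointly.  Models are fitted in increasing
#' complexity, each warm-started from the previous fit, and the nested
#' null's optimum is always included among the candidate solutions so the
#' nesting inequalities lnL(M1a) >= lnL(M0), lnL(M2a) >= lnL(M1a) and
#' lnL(M8) >= lnL(M7) hold for every fit.  The beta distribution of M7/M8
#' is discretized into \code{K} equal-probability categories at their
#' conditional means.
#'
#' @inheritParams codonLogLik
#' @param models character subset of c("M0", "M1a", "M2a", "M7", "M8").
#' @param K number of beta categories (default 10).
#' @param estimateScale estimate the global branch-length multiplier
#'   (default TRUE); when FALSE the multiplier is fixed at 1.
#' @return Named list, one element per model:
#'   \code{list(lnL, params, kappa, scale)}.
#' @export
fitSiteModels <- function(tree, aln,
                          models = c("M0", "M1a", "M2a", "M7", "M8"),
                          K = 10, estimateScale = TRUE) {
  models <- match.arg(models, several.ok = TRUE)
  .checkTree(tree)
  prep <- .codonTipPartials(tree, aln)
  pi <- f3x4Frequencies(aln)
  cache <- new.env(parent = emptyenv())

  fits <- list()
  w0guess <- 0.2
  kap0 <- log(2)
  sc0 <- 0
  prevTheta <- list()
  for (model in models) {
    spec <- .siteModelSpec(model, K)
    makeNegll <- function(spec) {
      function(par) {
        kap <- exp(par[1L])
        sc <- if (estimateScale) exp(par[2L]) else 1
        th <- par[-(1:(1L + estimateScale))]
        cl <- spec$classes(th)$classes
        ll <- tryCatch(
          .codonLogLikCore(tree, prep, kap, cl, pi, scale = sc,
                           cache = cache),
          error = function(e) -Inf)
        if (!is.finite(ll)) 1e10 else -ll
      }
    }
    negll <- makeNegll(spec)
    base <- if (estimateScale) c(kap0, sc0) else kap0
    starts <- list(c(base, spec$start(w0guess)))
    # warm starts connecting nested models (guarantee nesting numerically)
    warm <- switch(model,
      M1a = if (!is.null(fits$M0))
        list(c(base, .logit(0.95),
               .logit(min(max(fits$M0$params["omega"], 1e-3), 0.95)))),
      M2a = if (!is.null(fits$M1a))
        list(c(base, .logit(fits$M1a$params[["p0"]]), .logit(0.99),
               .logit(min(max(fits$M1a$params[["omega0"]], 1e-4),
                          1 - 1e-4)), log(1e-6))),
      M8 = if (!is.null(fits$M7))
        list(c(base, log(fits$M7$params[["p"]]), log(fits$M7$params[["q"]]),
               .logit(1 - 1e-6), log(1))),
      NULL)
    starts <- c(starts, warm)
    best <- .mlMaximize(negll, starts)
    kapHat <- exp(best$par[1L])
    scHat <- if (estimateScale) exp(best$par[2L]) else 1
    th <- best$par[-(1:(1L + estimateScale))]
    rep_ <- spec$classes(th)$report
    lnL <- -best$value
    # the nested optimum is itself a feasible point of the larger model
    null_lnL <- switch(model,
      M1a = fits$M0$lnL, M2a = fits$M1a$lnL, M8 = fits$M7$lnL, -Inf)
    if (!is.null(null_lnL) && is.finite(null_lnL) && lnL < null_lnL) {
      lnL <- null_lnL
      src <- switch(model, M1a = fits$M0, M2a = fits$M1a, M8 = fits$M7)
      kapHat <- src$kappa
      scHat <- src$scale
      rep_ <- switch(model,
        M1a = c(p0 = 1 - 1e-9, omega0 = unname(src$params["omega"])),
        M2a = c(p0 = unname(src$params["p0"]),
                p1 = unname(1 - src$params["p0"]) - 1e-9, p2 = 1e-9,
                omega0 = unname(src$params["omega0"]), omega2 = 1),
        M8 = c(p = unname(src$params["p"]), q = unname(src$params["q"]),
               p0 = 1 - 1e-9, omegaS = 1))
    }
    fits[[model]] <- list(lnL = lnL, params = rep_, kappa = kapHat,
                          scale = scHat)
    kap0 <- log(kapHat)
    sc0 <- log(scHat)
    if (model == "M0") w0guess <- unname(rep_["omega"])
  }
  fits
}

#' Fit branch-site model A
#'
#' Model A has four site classes.  Class 0: omega0 on all branches; class
#' 1: neutral everywhere; classes 2a/2b: omega0 (resp. 1) on background
#' branches but omega2 on the foreground branches.  H1 estimates
#' omega2 >= 1; H0 fixes omega2 = 1 (the null of the branch-site test of
#' positive selection, 1 df).
#'
#' @inheritParams fitSiteModels
#' @param foreground integer edge indices (rows of \code{tree$edge})
#'   marking foreground branches; see [stemEdge()].
#' @param hypothesis "H0" or "H1".
#' @return \code{list(lnL, params, kappa, scale, model)} where
#'   \code{model} is the fitted [branchSiteModel()].
#' @export
fitBranchSite <- function(tree, aln, foreground,
                          hypothesis = c("H1", "H0"),
                          estimateScale = TRUE) {
  hypothesis <- match.arg(hypothesis)
  .checkTree(tree)
  prep <- .codonTipPartials(tree, aln)
  pi <- f3x4Frequencies(aln)
  foreground <- as.integer(foreground)
  cache <- new.env(parent = emptyenv())

  buildClasses <- function(p0, p1, w0, w2) {
    rest <- max(1 - p0 - p1, 0)
    p2a <- rest * p0 / (p0 + p1)
    p2b <- rest * p1 / (p0 + p1)
    list(list(prop = p0, bg = w0, fg = w0),
         list(prop = p1, bg = 1, fg = 1),
         list(prop = p2a, bg = w0, fg = w2),
         list(prop = p2b, bg = 1, fg = w2))
  }
  nfix <- hypothesis == "H0"
  negll <- function(par) {
    kap <- exp(par[1L])
    sc <- if (estimateScale) exp(par[2L]) else 1
    i <- 1L + estimateScale
    p0 <- .invlogit(par[i + 1L])
    p1 <- (1 - p0) * .invlogit(par[i + 2L])
    w0 <- .invlogit(par[i + 3L])
    w2 <- if (nfix) 1 else 1 + exp(par[i + 4L])
    cl <- buildClasses(p0, p1, w0, w2)
    ll <- tryCatch(
      .codonLogLikCore(tree, prep, kap, cl, pi, scale = sc,
                       foreground = foreground, cache = cache),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  base <- if (estimateScale) c(log(2), 0) else log(2)
  mk <- function(p0, p1, w0, w2ex) {
    th <- c(.logit(p0), .logit(p1 / (1 - p0)), .logit(w0))
    if (!nfix) th <- c(th, log(w2ex))
    c(base, th)
  }
  starts <- list(mk(0.85, 0.1, 0.1, 0.5), mk(0.6, 0.2, 0.3, 2))
  best <- .mlMaximize(negll, starts)
  kapHat <- exp(best$par[1L])
  scHat <- if (estimateScale) exp(best$par[2L]) else 1
  i <- 1L + estimateScale
  p0 <- .invlogit(best$par[i + 1L])
  p1 <- (1 - p0) * .invlogit(best$par[i + 2L])
  w0 <- .invlogit(best$par[i + 3L])
  w2 <- if (nfix) 1 else 1 + exp(best$par[i + 4L])
  rest <- max(1 - p0 - p1, 0)
  props <- c(p0, p1, rest * p0 / (p0 + p1), rest * p1 / (p0 + p1))
  list(lnL = -best$value,
       params = c(p0 = p0, p1 = p1, p2a = props[3], p2b = props[4],
                  omega0 = w0, omega2 = w2),
       kappa = kapHat, scale = scHat,
       model = branchSiteModel(kapHat, props, w0, w2, foreground, pi))
}

#' Branch-site test of positive selection on foreground branches
#'
#' Fits H0 (foreground omega2 = 1) and H1 (omega2 >= 1 estimated) of
#' branch-site model A and returns the 1-df likelihood-ratio test.  H1 is
#' never reported worse than H0 (H0 is a feasible point of H1).
#'
#' @inheritParams fitBranchSite
#' @return \code{list(h0, h1, lrt)}.
#' @export
branchSiteTest <- function(tree, aln, foreground, estimateScale = TRUE) {
  h0 <- fitBranchSite(tree, aln, foreground, "H0",
                      estimateScale = estimateScale)
  h1 <- fitBranchSite(tree, aln, foreground, "H1",
                      estimateScale = estimateScale)
  if (h1$lnL < h0$lnL) {
    h1 <- h0
    h1$params["omega2"] <- 1
  }
  list(h0 = h0, h1 = h1, lrt = likelihoodRatioTest(h0$lnL, h1$lnL, df = 1))
}

# --- NG86 counting method ------------------------------------------------

# per-codon synonymous site count; changes to stop codons are excluded
# and the position renormalized
.ng86Sites <- function() {
  ce <- .codonSetup()
  if (!is.null(.codonEnv$sSites)) return(.codonEnv$sSites)
  nt <- c("T", "C", "A", "G")
  s <- numeric(length(ce$codons))
  for (i in seq_along(ce$codons)) {
    tot <- 0
    for (p in 1:3) {
      ch <- ce$letters[i, ]
      alts <- setdiff(nt, ch[p])
      syn <- 0
      ok <- 0
      for (a in alts) {
        ch2 <- ch
        ch2[p] <- a
        cod2 <- paste(ch2, collapse = "")
        if (cod2 %in% ce$stops) next
        ok <- ok + 1
        if (ce$aa[match(cod2, ce$codons)] == ce$aa[i]) syn <- syn + 1
      }
      if (ok > 0) tot <- tot + syn / ok
    }
    s[i] <- tot
  }
  names(s) <- ce$codons
  .codonEnv$sSites <- s
  s
}

# syn/nonsyn difference counts between two codons, averaged over all
# mutational pathways that avoid stop codons
.ng86Diffs <- function(c1, c2) {
  ce <- .codonSetup()
  if (c1 == c2) return(c(0, 0))
  ch1 <- strsplit(c1, "")[[1L]]
  ch2 <- strsplit(c2, "")[[1L]]
  d <- which(ch1 != ch2)
  perms <- if (length(d) == 1L) list(d) else {
    if (length(d) == 2L) list(d, rev(d)) else {
      do.call(c, lapply(1:3, function(i) {
        rest <- d[-i]
        list(c(d[i], rest), c(d[i], rev(rest)))
      }))
    }
  }
  acc <- c(0, 0)
  nOk <- 0
  for (ord in perms) {
    cur <- ch1
    sd <- 0
    nd <- 0
    valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- ch2[pos]
      codA <- paste(cur, collapse = "")
      codB <- paste(nxt, collapse = "")
      if (codB %in% ce$stops) {
        valid <- FALSE
        break
      }
      if (ce$aa[match(codA, ce$codons)] == ce$aa[match(codB, ce$codons)]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    if (valid) {
      acc <- acc + c(sd, nd)
      nOk <- nOk + 1
    }
  }
  if (nOk == 0) return(c(0, length(d)))  # all paths hit stops: count as NS
  acc / nOk
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Counts synonymous and nonsynonymous sites and differences per sequence
#' pair (averaging differences over stop-free mutational pathways),
#' applies the Jukes-Cantor correction \eqn{d = -\frac{3}{4}\ln(1 -
#' \frac{4}{3} p)}, and reports dN, dS and their ratio.  Used as a
#' counting-method sanity check of the ML omega estimates.  Codons with a
#' gap or ambiguity in either sequence are skipped for that pair.
#'
#' @param aln codon alignment without in-frame stops.
#' @return data.frame with columns id1, id2, dN, dS, omega (NA when the
#'   ratio is undefined, e.g. dS = 0).
#' @export
neiGojobori <- function(aln) {
  ce <- .codonSetup()
  m <- .alnToMatrix(aln)
  if (ncol(m) %% 3L != 0L) stop("alignment length not divisible by 3")
  .checkStops(m)
  sSites <- .ng86Sites()
  ids <- rownames(m)
  n <- length(ids)
  cod <- lapply(seq_len(n), function(i)
    apply(matrix(m[i, ], nrow = 3L), 2L, paste, collapse = ""))
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- cod[[i]] %in% ce$codons & cod[[j]] %in% ce$codons
      if (!any(ok)) next
      ci <- cod[[i]][ok]
      cj <- cod[[j]][ok]
      S <- (sum(sSites[ci]) + sum(sSites[cj])) / 2
      N <- 3 * length(ci) - S
      dif <- mapply(function(a, b) .ng86Diffs(a, b), ci, cj)
      Sd <- sum(dif[1L, ])
      Nd <- sum(dif[2L, ])
      jc <- function(p) {
        if (p >= 0.75) return(NA_real_)
        -0.75 * log(1 - 4 * p / 3)
      }
      dS <- if (S > 0) jc(Sd / S) else NA_real_
      dN <- if (N > 0) jc(Nd / N) else NA_real_
      omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        id1 = ids[i], id2 = ids[j], dN = dN, dS = dS, omega = omega)
    }
  }
  do.call(rbind, out)
}
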