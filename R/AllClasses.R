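setOldClass("phylo")
setOldClass("hclust")

#' Genome-by-gene-cluster presence/absence table
#'
#' Container for a binary gene-content matrix over a set of (possibly
#' partial) genome assemblies, together with the per-genome recovery
#' fraction estimated for each assembly and an optional per-genome marker
#' flag (e.g. \emph{narB} detected by PCR or annotation).
#'
#' @slot presence integer matrix, genomes as rows, gene clusters as columns,
#'   entries 0/1.
#' @slot recovery numeric vector, one value per genome in (0, 1]: estimated
#'   completeness of the assembly.
#' @slot marker logical vector, one value per genome (NA when unknown):
#'   whether the genome carries the marker gene of interest.
#'
#' @seealso [genePresenceTable()], [filterFlexible()], [markerEnrichment()]
#' @export
setClass("GenePresenceTable",
  representation(presence = "matrix", recovery = "numeric",
                 marker = "logical"))

setValidity("GenePresenceTable", function(object) {
  m <- object@presence
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    return("presence matrix must have genome row names and cluster column names")
  if (anyDuplicated(rownames(m))) return("genome ids must be unique")
  if (anyDuplicated(colnames(m))) return("gene cluster ids must be unique")
  if (!all(m %in% c(0L, 1L))) return("presence entries must be 0 or 1")
  if (length(object@recovery) != nrow(m))
    return("one recovery fraction per genome required")
  if (any(object@recovery <= 0 | object@recovery > 1))
    return("recovery fractions must lie in (0, 1]")
  if (length(object@marker) != nrow(m))
    return("one marker flag per genome required (NA allowed)")
  TRUE
})

#' Construct a GenePresenceTable
#'
#' @param presence binary matrix (genomes x gene clusters) with dimnames.
#' @param recovery per-genome recovery fraction in (0, 1]; recycled if a
#'   single value is given.
#' @param marker optional per-genome logical marker flag (default all NA).
#' @return A [GenePresenceTable-class] object.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("cA", "cB")))
#' genePresenceTable(m, recovery = 0.9)
#' @export
genePresenceTable <- function(presence, recovery = 1,
                              marker = NULL) {
  storage.mode(presence) <- "integer"
  if (length(recovery) == 1L) recovery <- rep(recovery, nrow(presence))
  recovery <- unname(recovery)
  if (is.null(marker)) marker <- rep(NA, nrow(presence))
  new("GenePresenceTable", presence = presence, recovery = recovery,
      marker = as.logical(marker))
}

#' Recombination parameter bundle in the ClonalFrame parameterization
#'
#' Holds, for one or more genomic regions, the primitive recombination
#' parameters estimated by ClonalFrameML-style inference: the
#' transition/transversion ratio kappa, the mean homologous import length
#' delta (bp), the per-site divergence nu of imported DNA, and the per-site
#' import initiation rate relative to mutation, R/theta.  The derived
#' quantities rho/theta = 2 R/theta and r/m = (R/theta) x delta x nu are
#' always recomputed from the primitives, never stored.
#'
#' @slot region character region labels.
#' @slot kappa,delta,nu,ROverTheta numeric primitives, one per region.
#' @seealso [recombinationParams()], [recombinationSummary()], [rOverM()]
#' @export
setClass("RecombinationParams",
  representation(region = "character", kappa = "numeric", delta = "numeric",
                 nu = "numeric", ROverTheta = "numeric"))

setValidity("RecombinationParams", function(object) {
  n <- length(object@region)
  if (any(lengths(list(object@kappa, object@delta, object@nu,
                       object@ROverTheta)) != n))
    return("all parameter vectors must have one entry per region")
  if (any(c(object@kappa, object@delta, object@nu, object@ROverTheta) < 0))
    return("all primitives must be non-negative")
  TRUE
})

#' @rdname RecombinationParams-class
#' @param region character labels for the regions.
#' @param kappa,delta,nu,ROverTheta numeric primitives (see class docs).
#' @return A [RecombinationParams-class] object.
#' @export
recombinationParams <- function(region, kappa, delta, nu, ROverTheta) {
  new("RecombinationParams", region = as.character(region),
      kappa = as.numeric(kappa), delta = as.numeric(delta),
      nu = as.numeric(nu), ROverTheta = as.numeric(ROverTheta))
}

#' Likelihood-ratio test result
#'
#' @slot lnLNull,lnLAlt log-likelihoods of the nested (null) and more
#'   general (alternative) model.
#' @slot statistic 2 (lnLAlt - lnLNull); reported even when negative.
#' @slot df degrees of freedom of the chi-squared reference.
#' @slot p upper-tail chi-squared probability.
#' @seealso [likelihoodRatioTest()]
#' @export
setClass("LrtResult",
  representation(lnLNull = "numeric", lnLAlt = "numeric",
                 statistic = "numeric", df = "numeric", p = "numeric"))

#' Ancestral reconstruction of a binary trait
#'
#' For parsimony, \code{states} holds a 0/1 indicator of which node states
#' occur in at least one most-parsimonious reconstruction, and \code{score}
#' is the minimum total weighted cost.  For maximum likelihood,
#' \code{states} holds per-node marginal posterior probabilities (rows sum
#' to 1) and \code{score} is the log-likelihood.
#'
#' @slot method "parsimony" or "ml".
#' @slot states numeric matrix with one row per node (tips first, then
#'   internal nodes, in ape numbering) and columns "0" and "1".
#' @slot score numeric: minimum cost (parsimony) or log-likelihood (ml).
#' @slot tree the phylogeny the reconstruction refers to.
#' @export
setClass("AncestralReconstruction",
  representation(method = "character", states = "matrix", score = "numeric",
                 tree = "phylo"))

setValidity("AncestralReconstruction", function(object) {
  if (!identical(colnames(object@states), c("0", "1")))
    return('states must have columns "0" and "1"')
  if (object@method == "ml" &&
      any(abs(rowSums(object@states) - 1) > 1e-9))
    return("marginal state probabilities must sum to 1 per node")
  TRUE
})

#' Result of a phylogenetic population-divergence permutation test
#'
#' @slot statistic "unifrac" or "ptest".
#' @slot observed the observed statistic (UniFrac fraction in [0,1], or the
#'   minimum parsimony change count).
#' @slot p permutation p-value, computed as (exceedances + 1)/(nIters + 1)
#'   so it is never exactly zero.
#' @slot nIters number of label permutations.
#' @slot seed RNG seed used for the permutations.
#' @export
setClass("DivergenceTestResult",
  representation(statistic = "character", observed = "numeric", p = "numeric",
                 nIters = "integer", seed = "integer"))

#' Two-state Markov (Mk) model of binary trait evolution
#'
#' @slot q01 trait gain rate (0 -> 1) per unit branch length.
#' @slot q10 trait loss rate (1 -> 0) per unit branch length.
#' @slot symmetric whether the one-parameter (MK1, q01 = q10) constraint is
#'   imposed.
#' @seealso [fitMk()], [mkLogLik()]
#' @export
setClass("MkModel",
  representation(q01 = "numeric", q10 = "numeric", symmetric = "logical"))

setValidity("MkModel", function(object) {
  if (object@q01 < 0 || object@q10 < 0) return("rates must be non-negative")
  if (object@symmetric && object@q01 != object@q10)
    return("symmetric model requires q01 == q10")
  TRUE
})

#' @rdname MkModel-class
#' @param q01,q10 gain and loss rates.
#' @param symmetric impose q01 = q10.
#' @return An [MkModel-class] object.
#' @export
mkModel <- function(q01, q10 = q01, symmetric = FALSE) {
  new("MkModel", q01 = q01, q10 = q10, symmetric = symmetric)
}

#' Membrane transport free-energy context
#'
#' Inputs for the free-energy cost of nutrient uptake,
#' \eqn{\Delta_r G = R T \ln([n]_I/[n]_E) + z F \Delta\Psi}.
#' The physical constants are fields (CODATA defaults) rather than
#' hard-coded so alternative unit systems can be tested.
#'
#' @slot gasConstant R, J mol^-1 K^-1.
#' @slot temperature T, K.
#' @slot nIn,nOut intracellular/extracellular nutrient concentration (same
#'   units, > 0).
#' @slot z unit charge of the nutrient species.
#' @slot faraday F, C mol^-1.
#' @slot deltaPsi membrane potential, V.
#' @seealso [transportFreeEnergy()]
#' @export
setClass("TransportContext",
  representation(gasConstant = "numeric", temperature = "numeric",
                 nIn = "numeric", nOut = "numeric", z = "numeric",
                 faraday = "numeric", deltaPsi = "numeric"))

setValidity("TransportContext", function(object) {
  if (object@temperature <= 0) return("temperature must be positive")
  if (object@nIn <= 0 || object@nOut <= 0)
    return("concentrations must be positive")
  TRUE
})

#' @rdname TransportContext-class
#' @param nIn,nOut,z,deltaPsi,temperature,gasConstant,faraday see class slots.
#' @return A [TransportContext-class] object.
#' @export
transportContext <- function(nIn, nOut, z = 0, deltaPsi = 0,
                             temperature = 298.15,
                             gasConstant = 8.314462618,
                             faraday = 96485.33212) {
  new("TransportContext", gasConstant = gasConstant,
      temperature = temperature, nIn = nIn, nOut = nOut, z = z,
      faraday = faraday, deltaPsi = deltaPsi)
}
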