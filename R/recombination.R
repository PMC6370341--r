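# ClonalFrame-style recombination summary statistics.  The inference of
# the primitives (kappa, delta, nu, R/theta) is consumed from an external
# tool's estimates; this module derives rho/theta and r/m from them and
# validates the derivation against the forward simulator's event log.

#' Relative impact of recombination versus mutation (r/m)
#'
#' The expected number of nucleotide changes introduced by homologous
#' recombination per point mutation: \eqn{r/m = (R/\theta) \times \delta
#' \times \nu}, where \eqn{R/\theta} is the per-site import initiation
#' rate relative to mutation, \eqn{\delta} the mean import length (bp)
#' and \eqn{\nu} the per-site divergence of imported DNA.
#'
#' @param ROverTheta,delta,nu non-negative primitives (vectorized).
#' @return \code{ROverTheta * delta * nu}.
#' @examples
#' rOverM(0.68, 4202, 0.012)  # ~34.3
#' @export
rOverM <- function(ROverTheta, delta, nu) {
  if (any(c(ROverTheta, delta, nu) < 0)) stop("inputs must be non-negative")
  ROverTheta * delta * nu
}

#' Population recombination rate relative to mutation (rho/theta)
#'
#' With \eqn{\rho = 2R}, \eqn{\rho/\theta = 2 \times R/\theta}.
#'
#' @param ROverTheta non-negative (vectorized).
#' @return \code{2 * ROverTheta}.
#' @examples
#' rhoOverTheta(0.68)  # 1.36
#' @export
rhoOverTheta <- function(ROverTheta) {
  if (any(ROverTheta < 0)) stop("input must be non-negative")
  2 * ROverTheta
}

#' Realized r/m from a forward-simulation event log
#'
#' Counts substituted sites inside recombinant imports over point
#' mutations across all branches of a
#' [simulateClonalFrameAlignment()] event log.  Over long simulations
#' this converges to \eqn{(R/\theta)\,\delta\,\nu}.
#'
#' @param eventLog data.frame with columns \code{type} ("mutation" or
#'   "import") and \code{nSub} (substituted sites; 1 for mutations).
#' @return Numeric ratio; 0 when there are no imports, NA (with a
#'   warning) when there are no mutations.
#' @export
realizedRmFromLog <- function(eventLog) {
  stopifnot(is.data.frame(eventLog), all(c("type", "nSub") %in%
                                           colnames(eventLog)))
  nMut <- sum(eventLog$type == "mutation")
  nRec <- sum(eventLog$nSub[eventLog$type == "import"])
  if (nMut == 0) {
    warning("no point mutations in event log: realized r/m undefined")
    return(NA_real_)
  }
  nRec / nMut
}

#' @rdname RecombinationParams-class
#' @aliases recombinationSummary,RecombinationParams-method
#' @export
setMethod("recombinationSummary", "RecombinationParams",
  function(object, published = NULL, tolerance = 0.05) {
    out <- data.frame(
      region = object@region,
      kappa = object@kappa,
      delta = object@delta,
      nu = object@nu,
      ROverTheta = object@ROverTheta,
      rhoOverTheta = rhoOverTheta(object@ROverTheta),
      rOverM = rOverM(object@ROverTheta, object@delta, object@nu))
    if (!is.null(published)) {
      out$published_rOverM <- published
      out$pct_deviation <- 100 * (out$rOverM - published) / published
      out$consistent <- abs(out$pct_deviation) <= 100 * tolerance
    }
    out
  })

#' Read a recombination parameter table from TSV
#'
#' Expects columns \code{region}, \code{kappa}, \code{delta}, \code{nu},
#' \code{R_over_theta} (a header row is required); any additional columns
#' are ignored.  A table with the published estimates for the nitrate
#' assimilation regions ships in
#' \code{system.file("extdata", "recombination_params.tsv", package =
#' "panphylo")}.
#'
#' @param path TSV path.
#' @return A [RecombinationParams-class].
#' @export
readRecombinationParams <- function(path) {
  tab <- read.delim(path)
  need <- c("region", "kappa", "delta", "nu", "R_over_theta")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  recombinationParams(tab$region, tab$kappa, tab$delta, tab$nu,
                      tab$R_over_theta)
}
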