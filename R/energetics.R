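# Free-energy cost of nutrient uptake transport, used in arguments about
# why increasingly oligotrophic niches make a transported nutrient more
# expensive to acquire.

#' Free-energy cost of nutrient uptake transport
#'
#' \deqn{\Delta_r G = R T \ln([n]_I/[n]_E) + z F \Delta\Psi}
#'
#' where \eqn{[n]_I} and \eqn{[n]_E} are the intra- and extracellular
#' nutrient concentrations, \eqn{z} the unit charge of the species and
#' \eqn{\Delta\Psi} the membrane potential.  As the environmental
#' concentration \eqn{[n]_E} falls, the uptake cost rises
#' logarithmically.
#'
#' @param ctx a [transportContext()].
#' @return \eqn{\Delta_r G} in J/mol, with attribute \code{kJ_per_mol}.
#' @examples
#' transportFreeEnergy(transportContext(nIn = 10, nOut = 1))
#' @export
transportFreeEnergy <- function(ctx) {
  stopifnot(is(ctx, "TransportContext"))
  validObject(ctx)
  g <- ctx@gasConstant * ctx@temperature * log(ctx@nIn / ctx@nOut) +
    ctx@z * ctx@faraday * ctx@deltaPsi
  attr(g, "kJ_per_mol") <- g / 1000
  g
}
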