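#' @rdname GenePresenceTable-class
#' @param object,x a \code{GenePresenceTable}.
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @rdname GenePresenceTable-class
#' @export
setGeneric("geneClusters", function(x) standardGeneric("geneClusters"))

#' @rdname GenePresenceTable-class
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname GenePresenceTable-class
#' @export
setGeneric("recovery", function(x) standardGeneric("recovery"))

#' @rdname GenePresenceTable-class
#' @export
setGeneric("markerFlag", function(x) standardGeneric("markerFlag"))

#' @rdname AncestralReconstruction-class
#' @param x an \code{AncestralReconstruction}.
#' @export
setGeneric("nodeStates", function(x) standardGeneric("nodeStates"))

#' @rdname RecombinationParams-class
#' @param object a \code{RecombinationParams} table.
#' @param published optional numeric vector of published r/m values to
#'   check the recomputation against.
#' @param tolerance relative deviation regarded as consistent with the
#'   published value (default 5\%, which absorbs the rounding of
#'   3-significant-figure published primitives).
#' @export
setGeneric("recombinationSummary",
           function(object, published = NULL, tolerance = 0.05)
             standardGeneric("recombinationSummary"))

#' @describeIn GenePresenceTable-class genome ids.
#' @export
setMethod("genomes", "GenePresenceTable", function(x) rownames(x@presence))

#' @describeIn GenePresenceTable-class gene-cluster ids.
#' @export
setMethod("geneClusters", "GenePresenceTable",
          function(x) colnames(x@presence))

#' @describeIn GenePresenceTable-class the binary matrix.
#' @export
setMethod("presenceMatrix", "GenePresenceTable", function(x) x@presence)

#' @describeIn GenePresenceTable-class per-genome recovery fractions.
#' @export
setMethod("recovery", "GenePresenceTable",
          function(x) setNames(x@recovery, rownames(x@presence)))

#' @describeIn GenePresenceTable-class per-genome marker flags.
#' @export
setMethod("markerFlag", "GenePresenceTable",
          function(x) setNames(x@marker, rownames(x@presence)))

#' @describeIn AncestralReconstruction-class the per-node state matrix.
#' @export
setMethod("nodeStates", "AncestralReconstruction", function(x) x@states)

setMethod("show", "GenePresenceTable", function(object) {
  cat("GenePresenceTable:", nrow(object@presence), "genomes x",
      ncol(object@presence), "gene clusters\n")
  cat("  median recovery:", format(median(object@recovery), digits = 3),
      "\n")
  mk <- object@marker
  if (any(!is.na(mk))) {
    cat("  marker+ genomes:", sum(mk, na.rm = TRUE), "of",
        sum(!is.na(mk)), "flagged\n")
  }
})

setMethod("show", "LrtResult", function(object) {
  cat("Likelihood-ratio test\n")
  cat(sprintf("  lnL null: %.4f  lnL alt: %.4f\n", object@lnLNull,
              object@lnLAlt))
  cat(sprintf("  statistic = %.4f on %g df, p = %.4g\n", object@statistic,
              object@df, object@p))
})

setMethod("show", "MkModel", function(object) {
  cat(sprintf("Mk model (%s): gain q01 = %.4g, loss q10 = %.4g\n",
              if (object@symmetric) "symmetric MK1" else "asymmetric Mk2",
              object@q01, object@q10))
})

setMethod("show", "AncestralReconstruction", function(object) {
  cat(sprintf("AncestralReconstruction (%s), %d nodes, score %.4f\n",
              object@method, nrow(object@states), object@score))
})

setMethod("show", "DivergenceTestResult", function(object) {
  cat(sprintf("%s: observed %.4g, permutation p = %.4g (%d iterations)\n",
              object@statistic, object@observed, object@p, object@nIters))
})

setMethod("show", "RecombinationParams", function(object) {
  print(recombinationSummary(object))
})
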