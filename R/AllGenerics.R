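# Generics, accessors and show methods.

#' Number of genes
#' @param x A WeightedDigraph, NetworkGenotype or SimulationParams.
#' @return Integer.
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname nGenes
#' @export
setMethod("nGenes", "WeightedDigraph", function(x) x@nGenes)
#' @rdname nGenes
#' @export
setMethod("nGenes", "NetworkGenotype", function(x) x@graph@nGenes)
#' @rdname nGenes
#' @export
setMethod("nGenes", "SimulationParams", function(x) x@nGenes)

#' Regulatory weight matrix
#' @param x A WeightedDigraph or NetworkGenotype.
#' @return Numeric matrix; entry (i, j) is the effect of gene j on gene i.
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "WeightedDigraph", function(x) x@weights)
#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "NetworkGenotype", function(x) x@graph@weights)

#' Intrinsic-noise genotype vector
#' @param x A NetworkGenotype.
#' @return Nonnegative numeric vector of per-gene noise variances.
#' @export
setGeneric("etaVector", function(x) standardGeneric("etaVector"))

#' @rdname etaVector
#' @export
setMethod("etaVector", "NetworkGenotype", function(x) x@eta)

#' Topology model label
#' @param x A WeightedDigraph.
#' @return One of "ER", "BA", "WS", "user".
#' @export
setGeneric("topologyModel", function(x) standardGeneric("topologyModel"))

#' @rdname topologyModel
#' @export
setMethod("topologyModel", "WeightedDigraph", function(x) x@topologyModel)

#' Final expression state of a realization
#' @param x A RealizationResult or EstablishmentResult.
#' @return Numeric expression vector.
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

#' @rdname finalState
#' @export
setMethod("finalState", "RealizationResult", function(x) x@finalState)
#' @rdname finalState
#' @export
setMethod("finalState", "EstablishmentResult", function(x) x@steadyState)

#' Stability flag of a realization
#' @param x A RealizationResult.
#' @return Logical; TRUE iff non-oscillating.
#' @export
setGeneric("isStable", function(x) standardGeneric("isStable"))

#' @rdname isStable
#' @export
setMethod("isStable", "RealizationResult", function(x) x@stable)

#' Analysis mask of intermediate-expression genes
#' @param x An EstablishmentResult or EvolutionRecord.
#' @return Logical vector, TRUE for genes strictly inside the expression
#'   bounds at the founder's steady state.
#' @export
setGeneric("intermediateMask", function(x) standardGeneric("intermediateMask"))

#' @rdname intermediateMask
#' @export
setMethod("intermediateMask", "EstablishmentResult",
          function(x) x@intermediateMask)
#' @rdname intermediateMask
#' @export
setMethod("intermediateMask", "EvolutionRecord", function(x) x@geneMask)

setMethod("show", "WeightedDigraph", function(object) {
  w <- object@weights
  cat(sprintf(
    "WeightedDigraph: %d genes, %d directed edges (%s model)\n",
    object@nGenes, sum(w != 0), object@topologyModel
  ))
  nz <- w[w != 0]
  if (length(nz))
    cat(sprintf("  weights in [%.3g, %.3g]\n", min(nz), max(nz)))
})

setMethod("show", "NetworkGenotype", function(object) {
  cat(sprintf(
    "NetworkGenotype: %d genes, %d edges; eta in [%.3g, %.3g]%s\n",
    object@graph@nGenes, sum(object@graph@weights != 0),
    min(object@eta), max(object@eta),
    if (all(object@eta == 0)) " (deterministic)" else ""
  ))
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(
    paste0(
      "SimulationParams: n=%d genes, N=%d, T=%d generations, Tr=%d steps\n",
      "  expression [%g, %g], basal %g; muEta=%g (N(%g,%g^2) replace),\n",
      "  muW=%g (N(%g,%g^2) additive), r=%g, tau=%d, epsilon=%g\n"
    ),
    object@nGenes, object@popSize, object@generations, object@Tr,
    object@sMin, object@sMax, object@sBasal, object@muEta,
    object@noiseMutMean, object@noiseMutSpread, object@muW, object@wMutMean,
    object@wMutSpread, object@recombRate, object@tau, object@epsilon
  ))
})

setMethod("show", "RealizationResult", function(object) {
  cat(sprintf(
    "RealizationResult: %d genes, %s (Phi=%.3g), %.2f%% draws clamped\n",
    length(object@finalState),
    if (object@stable) "stable" else "oscillating",
    object@phi, 100 * object@clampedFraction
  ))
})

setMethod("show", "EstablishmentResult", function(object) {
  cat(sprintf(
    paste0(
      "EstablishmentResult: %d genes, fitness %.4g\n",
      "  %d/%d genes at intermediate expression\n"
    ),
    length(object@steadyState), object@fitness,
    sum(object@intermediateMask), length(object@intermediateMask)
  ))
})

setMethod("show", "EvolutionRecord", function(object) {
  g <- object@generations
  cat(sprintf(
    paste0(
      "EvolutionRecord (%s): %d genes, generations 1..%d ",
      "(%d recorded)\n  mean fitness %.4g -> %.4g\n"
    ),
    object@mode, ncol(object@meanExpression), g[length(g)], length(g),
    object@meanFitness[1], object@meanFitness[length(g)]
  ))
})
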