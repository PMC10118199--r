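# S4 classes for the simulator's central objects.

#' Weighted directed regulatory network
#'
#' A square signed weight matrix over `nGenes` genes. Entry `weights[i, j]` is
#' the regulatory effect of gene `j` on gene `i` (positive = activation,
#' negative = repression, zero = no edge). The diagonal is zero (no
#' autoregulation) and the undirected skeleton (edge between i and j iff
#' `weights[i, j] != 0` or `weights[j, i] != 0`) is connected.
#'
#' @slot nGenes Integer number of genes (nodes).
#' @slot weights `nGenes x nGenes` numeric matrix of regulatory strengths.
#' @slot topologyModel One of `"ER"`, `"BA"`, `"WS"`, `"user"`.
#' @slot seed Integer seed used at generation time (`NA` for user graphs).
#' @slot weightRange Numeric length-2 range the nonzero weights were drawn
#'   from at generation time (informative only; mutation may leave it).
#' @seealso [generateTopology], [weightedDigraph]
#' @export
setClass("WeightedDigraph",
  representation(
    nGenes = "integer",
    weights = "matrix",
    topologyModel = "character",
    seed = "integer",
    weightRange = "numeric"
  ),
  prototype(
    topologyModel = "user",
    seed = NA_integer_,
    weightRange = c(-3, 3)
  )
)

setValidity("WeightedDigraph", function(object) {
  w <- object@weights
  n <- object@nGenes
  msg <- character()
  if (!is.numeric(w) || nrow(w) != n || ncol(w) != n)
    msg <- c(msg, sprintf("weights must be a %d x %d numeric matrix", n, n))
  else {
    if (any(!is.finite(w)))
      msg <- c(msg, "weights must be finite")
    if (any(diag(w) != 0))
      msg <- c(msg, "diagonal must be all zero (no autoregulation)")
    if (!.skeletonConnected(w))
      msg <- c(msg, "undirected skeleton must be connected")
  }
  if (!object@topologyModel %in% c("ER", "BA", "WS", "user"))
    msg <- c(msg, "topologyModel must be one of ER, BA, WS, user")
  if (length(msg)) msg else TRUE
})

# Weak connectivity of the skeleton; a single node is trivially connected.
.skeletonConnected <- function(w) {
  n <- nrow(w)
  if (n <= 1L) return(TRUE)
  skel <- (w != 0) | (t(w) != 0)
  g <- igraph::graph_from_adjacency_matrix(skel, mode = "undirected")
  igraph::is_connected(g)
}

#' Construct a WeightedDigraph from a weight matrix
#'
#' @param weights Square numeric matrix; `weights[i, j]` is the effect of gene
#'   `j` on gene `i`.
#' @param topologyModel Provenance label, default `"user"`.
#' @param seed Optional integer generation seed.
#' @param weightRange Optional weight range; defaults to the range of the
#'   nonzero entries.
#' @return A [WeightedDigraph-class] object.
#' @examples
#' w <- matrix(0, 2, 2); w[2, 1] <- 1
#' weightedDigraph(w)
#' @export
weightedDigraph <- function(weights, topologyModel = "user", seed = NA,
                            weightRange = NULL) {
  weights <- as.matrix(weights)
  dimnames(weights) <- NULL
  if (is.null(weightRange)) {
    nz <- weights[weights != 0]
    weightRange <- if (length(nz)) range(nz) else c(-3, 3)
  }
  new("WeightedDigraph",
    nGenes = nrow(weights), weights = weights,
    topologyModel = topologyModel, seed = as.integer(seed),
    weightRange = as.numeric(weightRange)
  )
}

#' Network genotype: regulatory matrix plus intrinsic noise vector
#'
#' One individual's heritable state: the regulatory network `graph` and the
#' intrinsic-noise vector `eta`, where `eta[i]` is the *variance* (squared
#' expression units) of the Gaussian draw governing gene i's per-step
#' expression level.
#'
#' @slot graph A [WeightedDigraph-class].
#' @slot eta Nonnegative numeric vector, one entry per gene.
#' @seealso [networkGenotype], [realize]
#' @export
setClass("NetworkGenotype",
  representation(graph = "WeightedDigraph", eta = "numeric")
)

setValidity("NetworkGenotype", function(object) {
  msg <- character()
  if (length(object@eta) != object@graph@nGenes)
    msg <- c(msg, "eta must have one entry per gene")
  if (any(!is.finite(object@eta)) || any(object@eta < 0))
    msg <- c(msg, "eta entries must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a NetworkGenotype
#'
#' @param graph A [WeightedDigraph-class].
#' @param eta Intrinsic-noise variance per gene; a scalar is recycled.
#'   Default 0 (deterministic genotype).
#' @return A [NetworkGenotype-class].
#' @examples
#' g <- generateTopology("ER", nGenes = 10, density = 0.15, seed = 1)
#' networkGenotype(g, eta = 100)
#' @export
networkGenotype <- function(graph, eta = 0) {
  n <- graph@nGenes
  eta <- rep_len(as.numeric(eta), n)
  new("NetworkGenotype", graph = graph, eta = eta)
}

#' Simulation parameters
#'
#' All model and evolution constants with their study defaults. Expression
#' levels live on \[`sMin`, `sMax`\] (default \[0, 100\]) around a basal level
#' `sBasal` (20). A realization iterates the network map for `Tr` steps (50).
#' Populations of `popSize` individuals evolve for `generations` rounds.
#' Noise-genotype mutations replace `eta` entries at rate `muEta` per gene per
#' replication with draws from Normal(`noiseMutMean`, `noiseMutSpread`^2)
#' clamped at zero; regulatory mutations perturb nonzero weights at rate `muW`
#' additively with Normal(`wMutMean`, `wMutSpread`^2) draws. Recombination
#' swaps eta tails at rate `recombRate` per offspring. Oscillation is judged
#' over the last `tau` steps with threshold `epsilon`. `rho` scales each
#' gene's fitness contribution; `sOpt` is the optimal expression vector
#' (empty until a stage sets it). Gene-level selective pressure uses mean-eta
#' trajectories sampled every `etaRecordStride` generations and the
#' responsiveness cut `pressureThreshold`.
#'
#' @seealso [simulationParams]
#' @export
setClass("SimulationParams",
  representation(
    nGenes = "integer", sBasal = "numeric", sMin = "numeric", sMax = "numeric",
    Tr = "integer", popSize = "integer", generations = "integer",
    muEta = "numeric", noiseMutMean = "numeric", noiseMutSpread = "numeric",
    muW = "numeric", wMutMean = "numeric", wMutSpread = "numeric",
    wMutKind = "character",
    recombRate = "numeric", tau = "integer", epsilon = "numeric",
    rho = "numeric", sOpt = "numeric",
    pressureThreshold = "numeric", etaRecordStride = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (!(object@sMin < object@sBasal && object@sBasal < object@sMax))
    msg <- c(msg, "must have sMin < sBasal < sMax")
  if (object@Tr <= object@tau)
    msg <- c(msg, "Tr must exceed tau")
  rates <- c(object@muEta, object@muW, object@recombRate)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "mutation/recombination rates must lie in [0, 1]")
  if (any(object@rho <= 0))
    msg <- c(msg, "rho entries must be positive")
  if (length(object@sOpt) &&
      length(object@sOpt) != object@nGenes)
    msg <- c(msg, "sOpt must be empty or one entry per gene")
  if (object@epsilon <= 0)
    msg <- c(msg, "epsilon must be positive")
  if (object@etaRecordStride < 1L)
    msg <- c(msg, "etaRecordStride must be >= 1")
  if (!object@wMutKind %in% c("additive", "replacement"))
    msg <- c(msg, "wMutKind must be 'additive' or 'replacement'")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationParams object
#'
#' @param nGenes Number of genes per network (40).
#' @param sBasal Basal expression level (20, expression units).
#' @param sMin,sMax Expression bounds (0, 100).
#' @param Tr Realization steps per generation (50).
#' @param popSize Population size N (1000).
#' @param generations Number of generations T (10000).
#' @param muEta Noise-genotype mutation rate per gene per replication (0.01).
#' @param noiseMutMean,noiseMutSpread Mean and standard deviation of the
#'   replacement distribution for eta mutations (100, 40).
#' @param muW Regulatory mutation rate per nonzero weight (0.1).
#' @param wMutMean,wMutSpread Mean and standard deviation of the
#'   Normal(0, 2^2) draw for regulatory mutations.
#' @param wMutKind `"additive"` (default): the draw perturbs the current
#'   weight; `"replacement"`: the draw replaces it. Under the additive
#'   reading weights random-walk over evolutionary time; under replacement
#'   they stay on the scale of the founding Uniform(-3, 3) draw. See the
#'   methods vignette for the consequences of each reading.
#' @param recombRate Recombination rate per offspring (0.05).
#' @param tau Window length for the oscillation criterion (10).
#' @param epsilon Oscillation threshold (1e-6).
#' @param rho Fitness contribution per gene; scalar recycled (1).
#' @param sOpt Optimal expression vector; empty until set by a stage.
#' @param pressureThreshold Responsiveness cut on selective pressure (0.5).
#' @param etaRecordStride Record eta trajectories every this many
#'   generations (2).
#' @return A [SimulationParams-class] object.
#' @examples
#' simulationParams(popSize = 100, generations = 500)
#' @export
simulationParams <- function(nGenes = 40, sBasal = 20, sMin = 0, sMax = 100,
                             Tr = 50, popSize = 1000, generations = 10000,
                             muEta = 0.01, noiseMutMean = 100,
                             noiseMutSpread = 40, muW = 0.1, wMutMean = 0,
                             wMutSpread = 2, wMutKind = "additive",
                             recombRate = 0.05, tau = 10,
                             epsilon = 1e-6, rho = 1, sOpt = numeric(0),
                             pressureThreshold = 0.5, etaRecordStride = 2) {
  new("SimulationParams",
    nGenes = as.integer(nGenes), sBasal = sBasal, sMin = sMin, sMax = sMax,
    Tr = as.integer(Tr), popSize = as.integer(popSize),
    generations = as.integer(generations), muEta = muEta,
    noiseMutMean = noiseMutMean, noiseMutSpread = noiseMutSpread,
    muW = muW, wMutMean = wMutMean, wMutSpread = wMutSpread,
    wMutKind = wMutKind,
    recombRate = recombRate, tau = as.integer(tau), epsilon = epsilon,
    rho = rep_len(as.numeric(rho), as.integer(nGenes)),
    sOpt = as.numeric(sOpt),
    pressureThreshold = pressureThreshold,
    etaRecordStride = as.integer(etaRecordStride)
  )
}

#' Result of realizing one genotype
#'
#' @slot finalState Length-n expression phenotype sampled at step `Tr`.
#' @slot stable Logical; TRUE iff the trajectory passes the oscillation
#'   criterion (Phi < epsilon over the last tau+1 steps).
#' @slot phi The oscillation statistic Phi at the final step.
#' @slot clampedFraction Fraction of per-step draws hitting a bound.
#' @slot trajectory `(Tr+1) x n` matrix of expression levels when retained,
#'   otherwise a 0-row matrix.
#' @seealso [realize]
#' @export
setClass("RealizationResult",
  representation(
    finalState = "numeric", stable = "logical", phi = "numeric",
    clampedFraction = "numeric", trajectory = "matrix"
  )
)

#' Outcome of the network establishment stage
#'
#' @slot genotype The highest-fitness stable [NetworkGenotype-class] of the
#'   final generation (eta all zero).
#' @slot steadyState Its deterministic expression state at step `Tr`.
#' @slot intermediateMask Logical per gene; TRUE iff the steady state lies
#'   strictly inside (`sMin`, `sMax`). Genes outside the mask are excluded
#'   from downstream analysis tables.
#' @slot fitness Fitness of the returned genotype.
#' @slot history Per-recorded-generation data.frame with columns
#'   `generation`, `meanFitness`, `bestFitness`, `fracStable`.
#' @slot params The [SimulationParams-class] used.
#' @slot seed Integer seed of the stage.
#' @seealso [establishNetwork]
#' @export
setClass("EstablishmentResult",
  representation(
    genotype = "NetworkGenotype", steadyState = "numeric",
    intermediateMask = "logical", fitness = "numeric",
    history = "data.frame", params = "SimulationParams", seed = "integer"
  )
)

#' Per-run record of a noise-evolution simulation
#'
#' Population summaries recorded at generation 1, at every
#' `etaRecordStride`-th generation, and at the final generation.
#'
#' @slot generations Strictly increasing integer vector of recorded
#'   generations, always containing 1 and the final generation.
#' @slot meanExpression,exprVariance `G x n` matrices of per-gene population
#'   mean expression and expression variance at the recorded generations.
#' @slot meanEta,medianEta `G x n` matrices of per-gene population mean and
#'   median intrinsic-noise genotype.
#' @slot meanFitness Length-G mean population fitness.
#' @slot mode `"selection"` or `"neutral"`.
#' @slot sOpt Optimal expression vector used for fitness.
#' @slot geneMask Logical per gene; analysis mask inherited from the founder
#'   (TRUE = intermediate expression).
#' @slot clampFraction Mean fraction of clamped draws over the run.
#' @slot seed Integer replicate seed.
#' @seealso [evolveNoise], [buildGeneTable]
#' @export
setClass("EvolutionRecord",
  representation(
    generations = "integer", meanExpression = "matrix",
    exprVariance = "matrix", meanEta = "matrix", medianEta = "matrix",
    meanFitness = "numeric", mode = "character", sOpt = "numeric",
    geneMask = "logical", clampFraction = "numeric", seed = "integer"
  )
)

setValidity("EvolutionRecord", function(object) {
  g <- object@generations
  msg <- character()
  if (length(g) < 2L || g[1] != 1L || any(diff(g) <= 0))
    msg <- c(msg, "generations must be strictly increasing and start at 1")
  dims <- vapply(
    list(object@meanExpression, object@exprVariance,
         object@meanEta, object@medianEta),
    function(m) identical(nrow(m), length(g)), logical(1)
  )
  if (!all(dims))
    msg <- c(msg, "summary matrices must have one row per recorded generation")
  if (!object@mode %in% c("selection", "neutral"))
    msg <- c(msg, "mode must be 'selection' or 'neutral'")
  if (length(msg)) msg else TRUE
})
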