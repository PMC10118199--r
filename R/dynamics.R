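# Realization of genotypes into expression phenotypes and stability checks.
#
# Dynamics: starting from the basal state s(0) = (sBasal, ..., sBasal), every
# gene is updated synchronously for Tr steps by
#   s_i(t+1) ~ Normal(sBasal + a_i(t), eta_i),   a_i(t) = sum_j w_ij s_j(t),
# with each draw hard-clamped to [sMin, sMax]. eta_i is the VARIANCE of the
# draw; with eta = 0 the map is deterministic and seed-independent.

#' Activation rates of all genes for a given expression state
#'
#' The additive regulatory input `a_i = sum_j w_ij s_j` (no cooperativity,
#' no clamping).
#'
#' @param graph A [WeightedDigraph-class].
#' @param state Numeric expression vector, one entry per gene.
#' @return Numeric vector of activation rates.
#' @examples
#' w <- matrix(0, 2, 2); w[2, 1] <- 1
#' activationRates(weightedDigraph(w), c(20, 20)) # c(0, 20)
#' @export
activationRates <- function(graph, state) {
  W <- graph@weights
  if (length(state) != nrow(W))
    stop("state must have one entry per gene")
  as.numeric(W %*% state)
}

# Phi statistic of the oscillation criterion at the last row of a trajectory:
# Phi = (1/tau) * sum_{theta = t-tau..t} D(S(theta), S(t)), where D is the
# mean absolute per-gene difference. The theta = t term is zero but is kept,
# matching the printed form of the criterion.
.trajectoryPhi <- function(trajectory, tau) {
  t <- nrow(trajectory)
  if (t < tau + 1L)
    stop("trajectory must have at least tau + 1 rows")
  ref <- trajectory[t, ]
  win <- trajectory[(t - tau):t, , drop = FALSE]
  d <- rowMeans(abs(sweep(win, 2L, ref)))
  sum(d) / tau
}

#' Oscillation criterion for an expression trajectory
#'
#' A trajectory is stable (non-oscillating) iff
#' `Phi = (1/tau) * sum_{theta=t-tau..t} D(S(theta), S(t)) < epsilon`,
#' where `t` is the final row and `D` the mean absolute per-gene difference.
#'
#' @param trajectory Matrix with one row per time step (at least `tau + 1`
#'   rows) and one column per gene.
#' @param tau Window length.
#' @param epsilon Threshold.
#' @return Logical: TRUE iff stable.
#' @examples
#' traj <- matrix(20, nrow = 11, ncol = 3)
#' stabilityCheck(traj, tau = 10, epsilon = 1e-6) # TRUE
#' @export
stabilityCheck <- function(trajectory, tau = 10, epsilon = 1e-6) {
  .trajectoryPhi(as.matrix(trajectory), as.integer(tau)) < epsilon
}

#' Realize a genotype into an expression phenotype
#'
#' Runs the stochastic network dynamics for `params@Tr` steps and samples the
#' phenotype at the last step. With an all-zero eta vector no random numbers
#' are consumed and the result is seed-independent.
#'
#' @param genotype A [NetworkGenotype-class].
#' @param params A [SimulationParams-class]; `nGenes` must match.
#' @param seed Integer seed for the stochastic draws (ignored when the
#'   genotype is deterministic). `NULL` uses the ambient RNG state.
#' @param keepTrajectory Retain the full `(Tr+1) x n` trajectory? Default
#'   FALSE (memory).
#' @return A [RealizationResult-class].
#' @examples
#' w <- matrix(0, 2, 2); w[2, 1] <- 1 # gene 1 activates gene 2
#' g <- networkGenotype(weightedDigraph(w), eta = 0)
#' finalState(realize(g, simulationParams(nGenes = 2))) # c(20, 40)
#' @export
realize <- function(genotype, params, seed = NULL, keepTrajectory = FALSE) {
  W <- genotype@graph@weights
  n <- nrow(W)
  if (params@nGenes != n)
    stop("params@nGenes does not match the genotype")
  eta <- genotype@eta
  sdv <- sqrt(eta)
  determ <- all(eta == 0)
  Tr <- params@Tr
  body <- function() {
    traj <- matrix(NA_real_, Tr + 1L, n)
    s <- rep(params@sBasal, n)
    traj[1L, ] <- s
    clamped <- 0L
    for (t in seq_len(Tr)) {
      mu <- params@sBasal + as.numeric(W %*% s)
      s <- if (determ) mu else mu + sdv * rnorm(n)
      clamped <- clamped + sum(s < params@sMin | s > params@sMax)
      s <- pmin(pmax(s, params@sMin), params@sMax)
      traj[t + 1L, ] <- s
    }
    phi <- .trajectoryPhi(traj, params@tau)
    new("RealizationResult",
      finalState = s, stable = phi < params@epsilon, phi = phi,
      clampedFraction = clamped / (n * Tr),
      trajectory = if (keepTrajectory) traj else
        matrix(numeric(0), 0L, n)
    )
  }
  if (determ) body() else withSeed(seed, body())
}

#' Realize a collection of genotypes
#'
#' Each genotype is realized under an independent, seed-derived substream
#' (`deriveSeed(seed, k)` for the k-th genotype), so the result is
#' deterministic given `(seed, order)` and row k is bitwise identical to
#' `realize(genotypes[[k]], params, deriveSeed(seed, k))`.
#'
#' @param genotypes List of [NetworkGenotype-class] objects (non-empty).
#' @param params A [SimulationParams-class].
#' @param seed Integer root seed.
#' @return List with `expression` (N x n matrix of final states), `stable`
#'   (logical N), `phi` (numeric N) and `clampedFraction` (numeric N).
#' @export
realizePopulation <- function(genotypes, params, seed = NULL) {
  stopifnot(length(genotypes) >= 1L)
  n <- params@nGenes
  N <- length(genotypes)
  expr <- matrix(NA_real_, N, n)
  stable <- logical(N)
  phi <- numeric(N)
  clamped <- numeric(N)
  for (k in seq_len(N)) {
    r <- realize(genotypes[[k]], params,
                 seed = if (is.null(seed)) NULL else deriveSeed(seed, k))
    expr[k, ] <- r@finalState
    stable[k] <- r@stable
    phi[k] <- r@phi
    clamped[k] <- r@clampedFraction
  }
  list(expression = expr, stable = stable, phi = phi,
       clampedFraction = clamped)
}

#' Export a realized trajectory as tidy TSV
#'
#' Columns `t` (0-based time step), `gene` (1-based id), `level`.
#'
#' @param result A [RealizationResult-class] realized with
#'   `keepTrajectory = TRUE`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(result, path) {
  traj <- result@trajectory
  if (nrow(traj) == 0L)
    stop("realization was run without keepTrajectory = TRUE")
  df <- data.frame(
    t = rep(seq_len(nrow(traj)) - 1L, times = ncol(traj)),
    gene = rep(seq_len(ncol(traj)), each = nrow(traj)),
    level = as.vector(traj)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export / import a genotype (JSON eta vector + adjacency TSV)
#'
#' @param genotype A [NetworkGenotype-class].
#' @param etaPath Path for the JSON eta vector.
#' @param adjacencyPath Path for the adjacency TSV
#'   (see [writeAdjacencyMatrix]).
#' @return `writeGenotype` returns `invisible(NULL)`; `readGenotype` returns a
#'   [NetworkGenotype-class].
#' @export
writeGenotype <- function(genotype, etaPath, adjacencyPath) {
  jsonlite::write_json(genotype@eta, etaPath, digits = NA)
  writeAdjacencyMatrix(genotype@graph, adjacencyPath)
  invisible(NULL)
}

#' @rdname writeGenotype
#' @export
readGenotype <- function(etaPath, adjacencyPath) {
  eta <- as.numeric(jsonlite::read_json(etaPath, simplifyVector = TRUE))
  networkGenotype(readAdjacencyMatrix(adjacencyPath), eta = eta)
}
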