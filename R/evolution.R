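# The two evolutionary stages: deterministic network establishment and
# stochastic noise evolution, plus the per-generation operators
# (fitness, selection, mutation, recombination).
#
# Per-generation event order in both stages: realize -> fitness ->
# reproduce -> mutate (-> recombine, noise stage only).

#' Stabilizing-selection fitness of an expression phenotype
#'
#' `F = exp(-sum_i |sOpt_i - s_i| / (n * rho_i))` over the genes in
#' `geneMask`, with `n` the number of masked genes. `F = 1` iff the phenotype
#' equals the optimum on every masked gene.
#'
#' @param state Expression vector (or n x N matrix, one column per
#'   individual).
#' @param sOpt Optimal expression vector.
#' @param rho Positive fitness-contribution weights; scalar recycled.
#' @param geneMask Optional logical vector restricting the sum.
#' @return Numeric fitness in (0, 1] (length N for a matrix input).
#' @examples
#' phenotypeFitness(c(48, 50), c(50, 50), rho = 1) # exp(-1)
#' @export
phenotypeFitness <- function(state, sOpt, rho = 1, geneMask = NULL) {
  state <- if (is.matrix(state)) state else matrix(state, ncol = 1L)
  n <- nrow(state)
  if (length(sOpt) != n)
    stop("sOpt must have one entry per gene")
  rho <- rep_len(as.numeric(rho), n)
  if (any(rho <= 0)) stop("rho entries must be positive")
  keep <- if (is.null(geneMask)) rep(TRUE, n) else as.logical(geneMask)
  if (!any(keep)) stop("geneMask excludes every gene")
  nm <- sum(keep)
  dev <- abs(state[keep, , drop = FALSE] - sOpt[keep]) / (nm * rho[keep])
  f <- exp(-colSums(dev))
  if (ncol(state) == 1L) f[[1L]] else f
}

#' Fitness-proportional (Wright-Fisher) reproduction
#'
#' Draws N offspring parents with replacement: under `"selection"`, parent k
#' is chosen with probability `fitness[k] / sum(fitness)`; under `"neutral"`
#' the draw is uniform regardless of fitness. Offspring are copies of their
#' parents, so the return value is the vector of parent indices.
#'
#' @param fitness Numeric vector of nonnegative fitnesses (length N >= 2).
#' @param mode `"selection"` or `"neutral"`.
#' @param seed Optional integer seed.
#' @return Integer vector of N parent indices.
#' @export
selectReproduce <- function(fitness, mode = c("selection", "neutral"),
                            seed = NULL) {
  mode <- match.arg(mode)
  N <- length(fitness)
  stopifnot(N >= 2L)
  if (mode == "selection" && all(fitness == 0))
    stop("all fitnesses are zero: no individual can reproduce")
  withSeed(seed,
    sample.int(N, N, replace = TRUE,
               prob = if (mode == "selection") fitness else NULL)
  )
}

#' Mutate the intrinsic-noise genotypes of a population
#'
#' Each (gene, individual) entry mutates independently with probability
#' `muEta`; a mutated entry is REPLACED by a draw from
#' Normal(`mean`, `spread`^2) clamped below at 0 (eta is a variance).
#'
#' @param eta Numeric vector or n x N matrix of noise genotypes.
#' @param muEta Mutation rate per gene per replication.
#' @param mean,spread Mean and standard deviation of the replacement draw
#'   (defaults 100, 40).
#' @param seed Optional integer seed.
#' @return Object of the same shape as `eta`.
#' @export
mutateNoise <- function(eta, muEta, mean = 100, spread = 40, seed = NULL) {
  stopifnot(muEta >= 0, muEta <= 1)
  if (muEta == 0) return(eta)
  withSeed(seed, {
    hit <- runif(length(eta)) < muEta
    k <- sum(hit)
    if (k > 0) eta[hit] <- pmax(0, rnorm(k, mean, spread))
    eta
  })
}

#' Mutate regulatory strengths, preserving the topology
#'
#' Only currently nonzero weights are eligible; each mutates independently
#' with probability `muW`. Under `kind = "additive"` (default) the mutated
#' weight is the current weight plus a Normal(`mean`, `spread`^2)
#' perturbation; under `kind = "replacement"` the draw replaces the weight.
#' A mutated weight landing exactly on zero is nudged by machine epsilon so
#' the edge set never changes.
#'
#' @param weights Numeric matrix (one network) or 3-d array `n x n x N`
#'   (population) of regulatory strengths.
#' @param muW Mutation rate per nonzero entry per replication.
#' @param mean,spread Mean and standard deviation of the mutation draw
#'   (defaults 0, 2).
#' @param kind `"additive"` or `"replacement"`.
#' @param seed Optional integer seed.
#' @return Object of the same shape as `weights`.
#' @export
mutateRegulatory <- function(weights, muW, mean = 0, spread = 2,
                             kind = c("additive", "replacement"),
                             seed = NULL) {
  stopifnot(muW >= 0, muW <= 1)
  kind <- match.arg(kind)
  if (muW == 0) return(weights)
  withSeed(seed, {
    eligible <- which(weights != 0)
    if (length(eligible) == 0L) return(weights)
    hit <- eligible[runif(length(eligible)) < muW]
    if (length(hit)) {
      draw <- rnorm(length(hit), mean, spread)
      w <- if (kind == "additive") weights[hit] + draw else draw
      w[w == 0] <- .Machine$double.eps
      weights[hit] <- w
    }
    weights
  })
}

# Mutation pass over a dense value matrix where every entry is an eligible
# (structurally nonzero) weight; used on the N x E establishment layout.
.mutateValues <- function(v, mu, mean, spread, kind) {
  hit <- runif(length(v)) < mu
  k <- sum(hit)
  if (k > 0) {
    draw <- rnorm(k, mean, spread)
    w <- if (kind == "additive") v[hit] + draw else draw
    w[w == 0] <- .Machine$double.eps
    v[hit] <- w
  }
  v
}

#' Recombine noise genotypes within a population
#'
#' Each offspring is selected independently with probability `rate`; for each
#' selected individual a partner is drawn uniformly from the other offspring,
#' a breakpoint `b` in `1..n-1` is drawn uniformly, and the eta entries at
#' loci `> b` are swapped between the pair (single pass in individual order;
#' partners may take part in several events). The regulatory matrix is never
#' recombined, and the per-locus multiset of eta values across the population
#' is conserved.
#'
#' @param eta `n x N` matrix of noise genotypes (N >= 2).
#' @param rate Recombination rate per offspring.
#' @param seed Optional integer seed.
#' @param pairs,breakpoints Optional explicit event list (matrix of
#'   individual pairs, one row per event, and integer breakpoints), mainly
#'   for deterministic reproduction of single events; when supplied, `rate`
#'   and the RNG are not consulted.
#' @return The recombined `n x N` matrix.
#' @export
recombineNoise <- function(eta, rate, seed = NULL, pairs = NULL,
                           breakpoints = NULL) {
  stopifnot(is.matrix(eta), ncol(eta) >= 2L)
  n <- nrow(eta)
  N <- ncol(eta)
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    breakpoints <- as.integer(breakpoints)
    stopifnot(length(breakpoints) == nrow(pairs),
              all(breakpoints >= 1L), all(breakpoints <= n - 1L))
    for (ev in seq_len(nrow(pairs))) {
      sel <- (breakpoints[ev] + 1L):n
      tmp <- eta[sel, pairs[ev, 1L]]
      eta[sel, pairs[ev, 1L]] <- eta[sel, pairs[ev, 2L]]
      eta[sel, pairs[ev, 2L]] <- tmp
    }
    return(eta)
  }
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || n < 2L) return(eta)
  withSeed(seed, {
    chosen <- which(runif(N) < rate)
    for (k in chosen) {
      partner <- sample.int(N - 1L, 1L)
      if (partner >= k) partner <- partner + 1L
      b <- sample.int(n - 1L, 1L)
      sel <- (b + 1L):n
      tmp <- eta[sel, k]
      eta[sel, k] <- eta[sel, partner]
      eta[sel, partner] <- tmp
    }
    eta
  })
}

#' Network establishment: evolve regulatory strengths toward intermediate
#' expression
#'
#' Starting from `popSize` copies of the founding topology, runs
#' `generations` rounds of deterministic realization (all eta = 0), fitness
#' toward the target `sOpt = sMax/2` for every gene, fitness-proportional
#' reproduction, and additive regulatory mutation on the nonzero weights
#' (topology preserved; no recombination). Oscillating individuals (Phi >=
#' epsilon) receive fitness 0 and cannot reproduce; if a whole generation
#' oscillates the run aborts with an error, matching the policy of discarding
#' oscillatory network configurations. The highest-fitness stable individual
#' of the final generation is returned (ties broken by lowest index),
#' together with its deterministic steady state and the mask of genes with
#' intermediate expression (strictly inside the bounds); genes on a bound are
#' flagged for exclusion from downstream analysis.
#'
#' @param graph Founding [WeightedDigraph-class] (connected).
#' @param params A [SimulationParams-class]; `popSize` and `generations` set
#'   the stage scale.
#' @param seed Integer seed.
#' @param recordEvery History stride in generations (default 50; generation 1
#'   and the final generation are always recorded).
#' @return An [EstablishmentResult-class].
#' @export
establishNetwork <- function(graph, params, seed = NULL, recordEvery = 50) {
  n <- graph@nGenes
  if (params@nGenes != n)
    stop("params@nGenes does not match the graph")
  W0 <- graph@weights
  idx <- which(W0 != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("graph has no edges")
  ei <- idx[, 1L] - 1L # regulated gene (row)
  ej <- idx[, 2L] - 1L # regulator (column)
  E <- nrow(idx)
  N <- params@popSize
  G <- params@generations
  sOpt <- rep((params@sMin + params@sMax) / 2, n)
  rho <- params@rho
  wv <- matrix(rep(W0[idx], each = N), nrow = N) # N x E, row = individual
  recGens <- sort(unique(c(1L, seq(1L, G, by = as.integer(recordEvery)), G)))
  hist <- data.frame(
    generation = recGens, meanFitness = NA_real_,
    bestFitness = NA_real_, fracStable = NA_real_
  )
  withSeed(seed, {
    final <- NULL
    fit <- NULL
    for (gen in seq_len(G)) {
      res <- .realizeDetermBatch(ei, ej, wv, n, params@sBasal, params@sMin,
                                 params@sMax, params@Tr, params@tau)
      states <- res$final # n x N
      stable <- res$phi < params@epsilon
      fit <- exp(-colSums(abs(states - sOpt) / (n * rho)))
      fit[!stable] <- 0
      if (all(fit == 0))
        stop(sprintf(
          "establishment aborted: every individual oscillates at generation %d",
          gen
        ))
      r <- match(gen, recGens)
      if (!is.na(r)) {
        hist$meanFitness[r] <- mean(fit)
        hist$bestFitness[r] <- max(fit)
        hist$fracStable[r] <- mean(stable)
      }
      if (gen == G) {
        final <- states
        break
      }
      parents <- sample.int(N, N, replace = TRUE, prob = fit)
      wv <- .mutateValues(wv[parents, , drop = FALSE], params@muW,
                          params@wMutMean, params@wMutSpread,
                          params@wMutKind)
    }
    best <- which.max(fit) # ties: lowest index (which.max convention)
    Wbest <- matrix(0, n, n)
    Wbest[idx] <- wv[best, ]
    steady <- final[, best]
    mask <- steady > params@sMin & steady < params@sMax
    new("EstablishmentResult",
      genotype = networkGenotype(
        weightedDigraph(Wbest,
          topologyModel = graph@topologyModel,
          seed = graph@seed, weightRange = graph@weightRange
        ),
        eta = 0
      ),
      steadyState = steady, intermediateMask = mask,
      fitness = fit[best], history = hist, params = params,
      seed = as.integer(if (is.null(seed)) NA else seed)
    )
  })
}

#' Noise evolution: evolve the intrinsic-noise genotype on a fixed network
#'
#' The regulatory matrix of the established founder is immutable; only the
#' eta vectors evolve. The starting population consists of `popSize` copies
#' of the founder whose eta vectors are drawn entrywise from
#' Normal(`noiseMutMean`, `noiseMutSpread`^2) clamped at 0. Each generation
#' performs stochastic realization, fitness toward `sOpt` (the founder's
#' deterministic steady state, frozen; constant fitness under `"neutral"`),
#' fitness-proportional reproduction, eta mutation, and recombination.
#' Fitness sums over all genes: boundary genes are harmless there because
#' their optimum equals their boundary steady state, and they are excluded
#' later, via the gene mask, from analysis tables only.
#'
#' @param founder An [EstablishmentResult-class], or a stable deterministic
#'   [NetworkGenotype-class] (its steady state is then computed here and an
#'   oscillating genotype is refused).
#' @param params A [SimulationParams-class]; `popSize` and `generations` set
#'   the stage scale.
#' @param mode `"selection"` or `"neutral"`.
#' @param seed Integer replicate seed.
#' @return An [EvolutionRecord-class].
#' @export
evolveNoise <- function(founder, params, mode = c("selection", "neutral"),
                        seed = NULL) {
  mode <- match.arg(mode)
  if (is(founder, "EstablishmentResult")) {
    W <- founder@genotype@graph@weights
    sOpt <- founder@steadyState
    mask <- founder@intermediateMask
  } else if (is(founder, "NetworkGenotype")) {
    if (any(founder@eta != 0))
      stop("founder genotype must be deterministic (eta all zero)")
    r <- realize(founder, params)
    if (!r@stable)
      stop("founder genotype oscillates; establish a stable network first")
    W <- founder@graph@weights
    sOpt <- r@finalState
    mask <- sOpt > params@sMin & sOpt < params@sMax
  } else {
    stop("founder must be an EstablishmentResult or NetworkGenotype")
  }
  n <- nrow(W)
  if (params@nGenes != n)
    stop("params@nGenes does not match the founder")
  N <- params@popSize
  G <- params@generations
  rho <- params@rho
  # an unseeded call draws its root from the ambient RNG so the run is still
  # internally coherent (kernel seeds derive from the same root)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  recGens <- sort(unique(c(
    1L, seq(1L, G, by = params@etaRecordStride), G
  )))
  nRec <- length(recGens)
  meanExpr <- matrix(NA_real_, nRec, n)
  varExpr <- matrix(NA_real_, nRec, n)
  meanEta <- matrix(NA_real_, nRec, n)
  medEta <- matrix(NA_real_, nRec, n)
  meanFit <- numeric(nRec)
  clampTot <- 0
  withSeed(
    deriveSeed(seed, "noise-evolution"),
    {
      eta <- matrix(
        pmax(0, rnorm(n * N, params@noiseMutMean, params@noiseMutSpread)),
        n, N
      )
      for (gen in seq_len(G)) {
        res <- .realizeStochShared(W, sqrt(eta), params@sBasal, params@sMin,
                                   params@sMax, params@Tr,
                                   deriveSeed(seed, "kernel", gen))
        states <- res$final # n x N
        clampTot <- clampTot + res$clampedFraction
        fit <- if (mode == "selection") {
          exp(-colSums(abs(states - sOpt) / (n * rho)))
        } else {
          rep(1, N)
        }
        r <- match(gen, recGens)
        if (!is.na(r)) {
          mu <- rowMeans(states)
          meanExpr[r, ] <- mu
          varExpr[r, ] <- (rowSums(states^2) - N * mu^2) / (N - 1)
          meanEta[r, ] <- rowMeans(eta)
          medEta[r, ] <- apply(eta, 1L, median)
          meanFit[r] <- mean(fit)
        }
        if (gen == G) break
        parents <- sample.int(N, N, replace = TRUE,
                              prob = if (mode == "selection") fit else NULL)
        eta <- eta[, parents, drop = FALSE]
        hit <- runif(n * N) < params@muEta
        k <- sum(hit)
        if (k > 0)
          eta[hit] <- pmax(0, rnorm(k, params@noiseMutMean,
                                    params@noiseMutSpread))
        eta <- .recombineInPlace(eta, params@recombRate)
      }
      new("EvolutionRecord",
        generations = recGens, meanExpression = meanExpr,
        exprVariance = varExpr, meanEta = meanEta, medianEta = medEta,
        meanFitness = meanFit, mode = mode, sOpt = sOpt, geneMask = mask,
        clampFraction = clampTot / G,
        seed = as.integer(seed)
      )
    }
  )
}

# recombineNoise without the seed scoping (runs inside the generation stream)
.recombineInPlace <- function(eta, rate) {
  if (rate == 0) return(eta)
  n <- nrow(eta)
  N <- ncol(eta)
  if (n < 2L) return(eta)
  chosen <- which(runif(N) < rate)
  for (k in chosen) {
    partner <- sample.int(N - 1L, 1L)
    if (partner >= k) partner <- partner + 1L
    b <- sample.int(n - 1L, 1L)
    sel <- (b + 1L):n
    tmp <- eta[sel, k]
    eta[sel, k] <- eta[sel, partner]
    eta[sel, partner] <- tmp
  }
  eta
}

#' Export an EvolutionRecord as tidy TSV
#'
#' Long format with columns `generation`, `gene`, `statistic`
#' (`mean_expression`, `expr_variance`, `mean_eta`, `median_eta`), `value`,
#' plus `mean_fitness` rows with `gene = NA`.
#'
#' @param record An [EvolutionRecord-class].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeEvolutionRecord <- function(record, path) {
  g <- record@generations
  n <- ncol(record@meanExpression)
  longOne <- function(m, name) {
    data.frame(
      generation = rep(g, times = n),
      gene = rep(seq_len(n), each = length(g)),
      statistic = name, value = as.vector(m)
    )
  }
  df <- rbind(
    longOne(record@meanExpression, "mean_expression"),
    longOne(record@exprVariance, "expr_variance"),
    longOne(record@meanEta, "mean_eta"),
    longOne(record@medianEta, "median_eta"),
    data.frame(
      generation = g, gene = NA_integer_,
      statistic = "mean_fitness", value = record@meanFitness
    )
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
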