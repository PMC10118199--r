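# Lazily built, cached simulation fixtures shared across test files.
#
# The heavy fixture reproduces the scaled study: 20 established ER networks
# (establishment N = 100, 1000 generations) and, on the first 10 founders,
# 3 selection + 3 neutral noise-evolution replicates (N = 200, T = 500).
# Built once per test run, on first use.

.fixtureCache <- new.env(parent = emptyenv())

established_fixture <- function() {
  if (!is.null(.fixtureCache$est)) return(.fixtureCache$est)
  seed <- 1
  pe <- simulationParams(popSize = 100, generations = 1000)
  ests <- list()
  attempts <- integer(0)
  att <- 0L
  while (length(ests) < 20L) {
    att <- att + 1L
    g <- generateTopology("ER", 40, 0.05,
                          seed = deriveSeed(seed, "topology", att))
    e <- tryCatch(
      establishNetwork(g, pe, seed = deriveSeed(seed, "establish", att)),
      error = function(x) NULL
    )
    if (is.null(e)) next
    ests[[length(ests) + 1L]] <- e
    attempts <- c(attempts, att)
  }
  .fixtureCache$est <- list(establishments = ests, attempts = attempts,
                            seed = seed, params = pe)
  .fixtureCache$est
}

noise_runs_fixture <- function() {
  if (!is.null(.fixtureCache$runs)) return(.fixtureCache$runs)
  base <- established_fixture()
  seed <- base$seed
  pn <- simulationParams(popSize = 200, generations = 500)
  ids <- sprintf("net%02d", 1:10)
  recs <- list()
  strengths <- list()
  masks <- list()
  for (i in 1:10) {
    est <- base$establishments[[i]]
    recs[[ids[i]]] <- list(
      selection = lapply(1:3, function(r) {
        evolveNoise(est, pn, "selection",
                    seed = deriveSeed(seed, "evolve", i, "selection", r))
      }),
      neutral = lapply(1:3, function(r) {
        evolveNoise(est, pn, "neutral",
                    seed = deriveSeed(seed, "evolve", i, "neutral", r))
      })
    )
    strengths[[ids[i]]] <- nodeStrengths(est@genotype@graph)
    masks[[ids[i]]] <- est@intermediateMask
  }
  geneSel <- buildGeneTable(lapply(recs, `[[`, "selection"), strengths, masks)
  geneNeu <- buildGeneTable(lapply(recs, `[[`, "neutral"), strengths, masks)
  .fixtureCache$runs <- list(
    records = recs, strengths = strengths, masks = masks,
    geneTableSelection = geneSel, geneTableNeutral = geneNeu,
    noiseParams = pn
  )
  .fixtureCache$runs
}

# A small established founder for cheap evolution tests (10 genes).
small_founder <- function() {
  if (!is.null(.fixtureCache$small)) return(.fixtureCache$small)
  p <- simulationParams(nGenes = 10, popSize = 50, generations = 200)
  g <- generateTopology("ER", 10, 0.2, seed = 404)
  .fixtureCache$small <- list(
    est = establishNetwork(g, p, seed = 405), params = p
  )
  .fixtureCache$small
}
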