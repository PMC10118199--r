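test_that("fitness follows the exponential distance-to-optimum form exactly", {
  expect_equal(phenotypeFitness(c(50, 50), c(50, 50)), 1)
  # n = 2, deviations (2, 0), rho = 1: exponent -(2/2) = -1
  expect_equal(phenotypeFitness(c(48, 50), c(50, 50)), exp(-1))
  # n = 40, all deviations 1: exponent -sum(1/40) = -1
  expect_equal(phenotypeFitness(rep(49, 40), rep(50, 40)), exp(-1))
  # rho rescales the per-gene contribution
  expect_equal(phenotypeFitness(c(48, 50), c(50, 50), rho = 2), exp(-0.5))
  # matrix input returns one fitness per column
  m <- cbind(c(50, 50), c(48, 50))
  expect_equal(phenotypeFitness(m, c(50, 50)), c(1, exp(-1)))
  # masked genes are excluded and the denominator shrinks with the mask
  expect_equal(
    phenotypeFitness(c(48, 0), c(50, 50), geneMask = c(TRUE, FALSE)),
    exp(-2)
  )
  expect_error(phenotypeFitness(c(1, 2), c(1, 2), rho = 0), "positive")
})

test_that("neutral reproduction is a uniform multinomial draw", {
  # 10^4 draws via repeated generations; fitness must be ignored
  draws <- unlist(lapply(1:1000, function(i) {
    selectReproduce(runif(10), "neutral", seed = i)
  }))
  tab <- table(factor(draws, levels = 1:10))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("selection probabilities are proportional to relative fitness", {
  draws <- unlist(lapply(1:1000, function(i) {
    selectReproduce(c(exp(-1), exp(-2)), "selection", seed = i)
  }))
  p1 <- mean(draws == 1L)
  target <- exp(1) / (exp(1) + 1) # e/(e+1)
  se <- sqrt(target * (1 - target) / length(draws))
  expect_lt(abs(p1 - target), 3 * se)
  expect_error(selectReproduce(c(0, 0), "selection"), "zero")
  expect_length(selectReproduce(runif(17), "selection", seed = 2), 17)
})

test_that("a fit lineage sweeps a population of unfit ones", {
  # one parent at the optimum, the rest far away: Wright-Fisher fixation
  fit <- c(1, rep(1e-6, 49))
  idx <- seq_len(50)
  set.seed(99)
  for (gen in 1:8) idx <- idx[selectReproduce(fit[idx], "selection")]
  expect_true(all(idx == 1L))
})

test_that("noise mutation replaces entries at the binomial rate", {
  eta <- matrix(100, 40, 1000)
  expect_identical(mutateNoise(eta, 0), eta)
  allMut <- mutateNoise(eta, 1, mean = 7, spread = 0, seed = 1)
  expect_true(all(allMut == 7))
  mut <- mutateNoise(eta, 0.01, seed = 2)
  k <- sum(mut != eta)
  expectK <- length(eta) * 0.01
  expect_lt(abs(k - expectK), 3 * sqrt(expectK * 0.99))
  expect_true(all(mut >= 0)) # negative draws clamp at zero
  low <- mutateNoise(matrix(100, 10, 10), 1, mean = -50, spread = 1, seed = 3)
  expect_true(all(low == 0))
})

test_that("regulatory mutation preserves the edge set under both kinds", {
  W <- weightMatrix(generateTopology("ER", 12, 0.15, seed = 6))
  expect_identical(mutateRegulatory(W, 0), W)
  expect_identical(mutateRegulatory(matrix(0, 3, 3), 0.5, seed = 1),
                   matrix(0, 3, 3))
  # zero-mean zero-spread additive perturbation changes nothing
  expect_equal(mutateRegulatory(W, 1, mean = 0, spread = 0,
                                kind = "additive", seed = 1), W)
  for (kind in c("additive", "replacement")) {
    Wm <- mutateRegulatory(W, 0.5, kind = kind, seed = 8)
    expect_identical(Wm != 0, W != 0)
  }
  # a replacement draw landing exactly on zero is nudged off zero
  Wr <- mutateRegulatory(W, 1, mean = 0, spread = 0, kind = "replacement",
                         seed = 1)
  expect_true(all(Wr[W != 0] == .Machine$double.eps))
})

test_that("recombination swaps eta tails and conserves per-locus multisets", {
  eta <- matrix(1:20, 4, 5) * 1.0
  expect_identical(recombineNoise(eta, 0), eta)
  swapped <- recombineNoise(eta, 1, pairs = cbind(1L, 2L),
                            breakpoints = 3L)
  expect_equal(swapped[4, 1:2], eta[4, 2:1]) # only the last locus swapped
  expect_equal(swapped[1:3, 1:2], eta[1:3, 1:2])
  set.seed(31)
  big <- matrix(runif(30 * 50), 30, 50)
  rec <- recombineNoise(big, 0.4, seed = 32)
  for (locus in seq_len(30)) {
    expect_equal(sort(rec[locus, ]), sort(big[locus, ]))
  }
})

test_that("establishment returns a stable genotype with a correct mask", {
  sf <- small_founder()
  est <- sf$est
  expect_s4_class(est, "EstablishmentResult")
  r <- realize(est@genotype, sf$params)
  expect_true(isStable(r))
  expect_identical(r@finalState, est@steadyState)
  expect_identical(est@intermediateMask,
                   est@steadyState > 0 & est@steadyState < 100)
  expect_true(all(est@history$fracStable >= 0))
  expect_gt(est@fitness, 0)
})

test_that("an already-optimal founder keeps fitness one", {
  # ring with weight 0.6: fixed point is exactly 50 for every gene
  g <- ring_graph(8, 0.6)
  p <- simulationParams(nGenes = 8, popSize = 20, generations = 10)
  est <- establishNetwork(g, p, seed = 1)
  expect_equal(est@fitness, 1)
  expect_equal(est@steadyState, rep(50, 8), tolerance = 1e-10)
  expect_true(all(est@intermediateMask))
})

test_that("a founder population that oscillates as a whole aborts", {
  g <- oscillating_graph()
  p <- simulationParams(nGenes = 2, popSize = 10, generations = 5, muW = 0)
  expect_error(establishNetwork(g, p, seed = 1), "oscillates")
  expect_error(evolveNoise(networkGenotype(g, 0),
                           simulationParams(nGenes = 2, popSize = 10,
                                            generations = 5)),
               "oscillates")
})

test_that("noise evolution records have the promised shape and determinism", {
  sf <- small_founder()
  p <- simulationParams(nGenes = 10, popSize = 40, generations = 31,
                        etaRecordStride = 2)
  r1 <- evolveNoise(sf$est, p, "selection", seed = 5)
  expect_s4_class(r1, "EvolutionRecord")
  g <- r1@generations
  expect_identical(g[1], 1L)
  expect_identical(g[length(g)], 31L)
  expect_true(all(diff(g) > 0))
  expect_identical(dim(r1@meanEta), c(length(g), 10L))
  expect_true(all(is.finite(r1@meanFitness)))
  r2 <- evolveNoise(sf$est, p, "selection", seed = 5)
  expect_identical(r1@meanExpression, r2@meanExpression)
  expect_identical(r1@meanEta, r2@meanEta)
  r3 <- evolveNoise(sf$est, p, "selection", seed = 6)
  expect_false(identical(r1@meanEta, r3@meanEta))
})

test_that("neutral noise evolution drifts around the mutation distribution", {
  sf <- small_founder()
  p <- simulationParams(nGenes = 10, popSize = 100, generations = 200)
  r <- evolveNoise(sf$est, p, "neutral", seed = 9)
  G <- nrow(r@meanEta)
  # no monotone trend in the pooled mean eta trajectory
  traj <- rowMeans(r@meanEta)
  mk <- suppressWarnings(cor.test(traj, seq_along(traj), method = "kendall"))
  expect_gt(mk$p.value, 0.01)
  # the final population sits near the replacement-mutation mean
  expect_lt(abs(mean(r@meanEta[G, ]) - 100), 20)
  # fitness is flat at the neutral constant
  expect_true(all(r@meanFitness == 1))
})

test_that("selection increases mean fitness and reduces noise genotypes", {
  sf <- small_founder()
  p <- simulationParams(nGenes = 10, popSize = 100, generations = 200)
  r <- evolveNoise(sf$est, p, "selection", seed = 12)
  G <- nrow(r@meanEta)
  early <- mean(r@meanFitness[1:(G %/% 4)])
  late <- mean(r@meanFitness[(3 * G %/% 4):G])
  expect_gt(late, early)
  expect_lt(median(r@medianEta[G, ]), median(r@medianEta[1, ]))
})
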