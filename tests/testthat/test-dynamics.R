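test_that("activation rates are the plain weighted sums of regulator levels", {
  wz <- weightedDigraph(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(activationRates(wz, c(5, 7)), c(7, 0))
  w2 <- matrix(0, 2, 2)
  w2[2, 1] <- 1
  expect_equal(activationRates(weightedDigraph(w2), c(20, 20)), c(0, 20))
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- -0.5
  w3[1, 3] <- 2
  w3[2, 1] <- 1 # keeps the skeleton connected
  expect_equal(activationRates(weightedDigraph(w3), c(10, 20, 30))[1], 50)
  expect_error(activationRates(wz, c(1, 2, 3)), "one entry per gene")
})

test_that("an isolated deterministic gene stays at the basal level", {
  g <- networkGenotype(weightedDigraph(matrix(0, 1, 1)), eta = 0)
  p <- simulationParams(nGenes = 1)
  r <- realize(g, p, keepTrajectory = TRUE)
  expect_true(all(r@trajectory == 20))
  expect_equal(finalState(r), 20)
  expect_true(isStable(r))
})

test_that("a single activating edge reaches its hand-computed steady state", {
  w <- matrix(0, 2, 2)
  w[2, 1] <- 1 # gene 1 activates gene 2: s2 -> 20 + 20 = 40
  g <- networkGenotype(weightedDigraph(w), eta = 0)
  r <- realize(g, simulationParams(nGenes = 2), keepTrajectory = TRUE)
  expect_equal(finalState(r), c(20, 40))
  expect_true(all(r@trajectory[-1, 1] == 20))
  expect_true(all(r@trajectory[-1, 2] == 40))
})

test_that("deterministic realization is seed-invariant, bitwise", {
  g <- networkGenotype(generateTopology("ER", 15, 0.15, seed = 5), eta = 0)
  p <- simulationParams(nGenes = 15)
  r1 <- realize(g, p, seed = 1)
  r2 <- realize(g, p, seed = 999)
  expect_identical(r1@finalState, r2@finalState)
})

test_that("every emitted expression value lies within the bounds", {
  for (s in 1:5) {
    g <- networkGenotype(generateTopology("ER", 12, 0.15, seed = s),
                         eta = 200)
    p <- simulationParams(nGenes = 12)
    r <- realize(g, p, seed = s, keepTrajectory = TRUE)
    expect_true(all(r@trajectory >= 0 & r@trajectory <= 100))
  }
})

test_that("the oscillation statistic matches hand-computed values", {
  phi <- grnoise:::.trajectoryPhi
  constant <- matrix(20, 11, 4)
  expect_equal(phi(constant, 10), 0)
  expect_true(stabilityCheck(constant, tau = 10, epsilon = 1e-6))
  # alternating all-20 / all-22 rows ending on 22, tau = 2:
  # terms D = 0 (theta=t), 2 (theta=t-1), 0 (theta=t-2); Phi = 2/2 = 1
  alt <- matrix(rep(c(20, 22), length.out = 7), 7, 3)
  expect_equal(phi(alt, 2), 1)
  expect_false(stabilityCheck(alt, tau = 2, epsilon = 1e-6))
  # geometric convergence with tail steps below epsilon/tau is stable
  conv <- matrix(50 + 1e-9 * 0.5^(0:12), 13, 1)
  expect_true(stabilityCheck(conv, tau = 10, epsilon = 1e-6))
  expect_error(phi(matrix(0, 5, 2), 10), "at least tau")
})

test_that("population realization matches per-genotype substreams bitwise", {
  g <- networkGenotype(generateTopology("ER", 8, 0.25, seed = 2), eta = 50)
  p <- simulationParams(nGenes = 8)
  pop <- realizePopulation(list(g, g, g), p, seed = 123)
  for (k in 1:3) {
    solo <- realize(g, p, seed = deriveSeed(123, k))
    expect_identical(pop$expression[k, ], solo@finalState)
    expect_identical(pop$stable[k], solo@stable)
  }
  # identical deterministic genotypes give identical rows
  gd <- networkGenotype(generateTopology("ER", 8, 0.25, seed = 2), eta = 0)
  popd <- realizePopulation(list(gd, gd, gd, gd), p, seed = 5)
  expect_true(all(apply(popd$expression, 2, function(col) {
    all(col == col[1])
  })))
})

test_that("terminal draws of an isolated noisy gene have variance eta", {
  g <- networkGenotype(weightedDigraph(matrix(0, 1, 1)), eta = 25)
  p <- simulationParams(nGenes = 1)
  pop <- realizePopulation(rep(list(g), 4000), p, seed = 8)
  v <- var(pop$expression[, 1])
  expect_lt(abs(v - 25) / 25, 0.1)
})

test_that("interior deterministic steady states solve the linear fixed point", {
  set.seed(42)
  for (rep in 1:5) {
    W <- weightMatrix(generateTopology("ER", 10, 0.2,
                                       seed = 100 + rep))
    W <- W * (0.7 / max(abs(eigen(W, only.values = TRUE)$values)))
    # contraction: unique interior fixed point unless clamped
    g <- networkGenotype(weightedDigraph(W), eta = 0)
    r <- realize(g, simulationParams(nGenes = 10))
    if (r@stable && all(r@finalState > 0 & r@finalState < 100)) {
      sLin <- solve(diag(10) - W, rep(20, 10))
      expect_lt(max(abs(r@finalState - sLin)), 1e-5)
    }
  }
})

test_that("genotype serialization round-trips eta and weights", {
  g <- networkGenotype(generateTopology("ER", 6, 0.3, seed = 4),
                       eta = c(0, 1, 2.5, 100, 40, 7))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeGenotype(g, f1, f2)
  g2 <- readGenotype(f1, f2)
  expect_identical(weightMatrix(g2), weightMatrix(g))
  expect_equal(etaVector(g2), etaVector(g))
})
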