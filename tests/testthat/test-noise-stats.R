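test_that("expression variance is the per-gene sample variance", {
  states <- rbind(c(10, 1), c(20, 1))
  expect_equal(expressionVariance(states), c(50, 0))
  same <- matrix(7, 5, 3)
  expect_equal(expressionVariance(same), c(0, 0, 0))
  expect_error(expressionVariance(matrix(1, 1, 3)), "at least 2")
})

test_that("relative variance change follows the normalized-difference form", {
  expect_equal(relativeVarianceChange(10, 10), 0)
  expect_equal(relativeVarianceChange(10, 0), 1)
  expect_equal(relativeVarianceChange(100, 25), 0.6)
  expect_equal(relativeVarianceChange(c(10, 100), c(10, 25)), c(0, 0.6))
  expect_warning(out <- relativeVarianceChange(c(0, 4), c(0, 2)), "zero")
  expect_true(is.na(out[1]))
  expect_equal(out[2], 1 / 3)
})

test_that("selective pressure averages the normalized eta reduction", {
  flat <- selectivePressure(c(100, 100, 100, 100))
  expect_equal(flat$pressure, 0)
  expect_false(flat$responsive)
  # immediate drop to half and stay: every term is 0.5, on the boundary
  half <- selectivePressure(c(100, 50, 50, 50))
  expect_equal(half$pressure, 0.5)
  expect_false(half$responsive) # strict >
  # early decay to zero approaches full pressure
  dec <- selectivePressure(c(100, rep(0, 99)))
  expect_equal(dec$pressure, 1)
  expect_true(dec$responsive)
  expect_error(selectivePressure(c(0, 10)), "positive")
  expect_error(selectivePressure(100), "at least 2")
})

test_that("mutual information matches closed forms and the entropy oracle", {
  # distinct values split into two equal-frequency bins: joint table is
  # diagonal with mass 1/2 each, so MI is exactly log 2
  x <- as.numeric(3:12)
  expect_equal(mutualInformation(x, x, bins = 2), log(2))
  # MI(x, x) equals the entropy of the binned variable
  set.seed(5)
  z <- rnorm(60)
  bins <- ceiling(60^(1 / 3))
  expect_equal(mutualInformation(z, z), bf_mutual_information(z, z, bins))
  # symmetry and agreement with the brute-force oracle on random inputs
  for (rep in 1:5) {
    a <- rnorm(40 + rep * 10)
    b <- 0.5 * a + rnorm(length(a))
    expect_equal(mutualInformation(a, b), mutualInformation(b, a))
    expect_equal(
      mutualInformation(a, b),
      bf_mutual_information(a, b, ceiling(round(length(a)^(1 / 3), 9)))
    )
    expect_gte(mutualInformation(a, b), 0)
  }
  expect_warning(expect_equal(mutualInformation(rep(1, 20), rnorm(20)), 0),
                 "constant")
  expect_error(mutualInformation(1:10, 1:11), "equal length")
})

test_that("an independent permuted copy carries no detectable information", {
  set.seed(9)
  x <- rnorm(200)
  y <- sample(x) # same margin, independent pairing
  obs <- mutualInformation(x, y)
  nullMI <- replicate(200, mutualInformation(x, sample(y)))
  expect_lt(obs, quantile(nullMI, 0.95))
})

test_that("the permutation p-value behaves at its boundaries and null", {
  set.seed(2)
  x <- rnorm(60)
  exact <- miPermutationTest(x, x, nPermutations = 199, seed = 4)
  expect_equal(exact$pValue, 1 / 200)
  # one group is the same as no grouping under the same seed
  y <- rnorm(60)
  a <- miPermutationTest(x, y, nPermutations = 199, seed = 5)
  b <- miPermutationTest(x, y, nPermutations = 199, seed = 5,
                         groupLabels = rep(1, 60))
  expect_identical(a$pValue, b$pValue)
  # p-values are uniform under independence
  set.seed(6)
  ps <- replicate(200, {
    u <- rnorm(30)
    v <- rnorm(30)
    miPermutationTest(u, v, nPermutations = 199,
                      seed = sample.int(1e6, 1))$pValue
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the gene table assembles, averages and filters as documented", {
  gens <- c(1L, 3L, 5L)
  # replicate pressures 0.4 and 0.8 for gene 1; gene 2 flat; gene 3 filtered
  repA <- make_record(gens,
    meanEta = cbind(c(100, 60, 60), c(100, 100, 100), c(100, 50, 50)),
    exprVariance = cbind(c(100, 50, 25), c(9, 9, 9), c(4, 4, 4))
  )
  repB <- make_record(gens,
    meanEta = cbind(c(100, 20, 20), c(100, 100, 100), c(100, 50, 50)),
    exprVariance = cbind(c(100, 50, 25), c(9, 9, 9), c(4, 4, 4))
  )
  strengths <- list(netA = data.frame(
    gene = 1:3, instrength = c(1, 2, 3), outstrength = c(3, 2, 1)
  ))
  masks <- list(netA = c(TRUE, TRUE, FALSE))
  tab <- buildGeneTable(list(netA = list(repA, repB)), strengths, masks)
  expect_identical(nrow(tab), 2L) # the masked-out gene is absent
  expect_false(3 %in% tab$gene)
  g1 <- tab[tab$gene == 1, ]
  expect_equal(g1$selective_pressure, 0.6) # mean of 0.4 and 0.8
  expect_true(g1$responsive) # thresholded after averaging
  expect_equal(g1$variance_gen1, 100)
  expect_equal(g1$variance_final, 25)
  expect_equal(g1$relative_variance_change, 0.6)
  g2 <- tab[tab$gene == 2, ]
  expect_equal(g2$selective_pressure, 0)
  expect_false(g2$responsive)
  # mismatched ids fail fast
  expect_error(buildGeneTable(list(other = list(repA)), strengths, masks),
               "match")
  # with includeFiltered the boundary gene is retained and flagged
  tabAll <- buildGeneTable(list(netA = list(repA, repB)), strengths, masks,
                           includeFiltered = TRUE)
  expect_identical(nrow(tabAll), 3L)
  expect_false(tabAll$intermediate_expression[3])
})

test_that("gene tables serialize with a stable column order", {
  gens <- c(1L, 2L)
  rec <- make_record(gens, meanEta = cbind(c(100, 40), c(100, 90)))
  tab <- buildGeneTable(
    list(net1 = rec),
    list(net1 = data.frame(gene = 1:2, instrength = 1:2, outstrength = 2:1))
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneTable(tab, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(names(back)[1:4],
                   c("network", "gene", "instrength", "outstrength"))
  expect_equal(back$selective_pressure, tab$selective_pressure)
})
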