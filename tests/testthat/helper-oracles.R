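# Independent oracles used only by the test suite.

# Floyd-Warshall all-pairs shortest paths on the unweighted directed edge set
# (edge iff weight nonzero; W[i, j] != 0 means edge j -> i).
fw_distances <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  idx <- which(W != 0, arr.ind = TRUE)
  d[cbind(idx[, 2], idx[, 1])] <- 1 # from regulator j to target i
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Asynchronous-update oracle: genes updated one at a time in random order
# until the state stops moving (or a sweep cap is reached).
async_fixed_point <- function(W, sBasal = 20, sMin = 0, sMax = 100,
                              maxSweeps = 500, tol = 1e-12, seed = 77) {
  n <- nrow(W)
  s <- rep(sBasal, n)
  set.seed(seed)
  for (sw in seq_len(maxSweeps)) {
    sOld <- s
    for (i in sample.int(n)) {
      s[i] <- min(max(sBasal + sum(W[i, ] * s), sMin), sMax)
    }
    if (max(abs(s - sOld)) < tol) break
  }
  s
}

# Brute-force mutual information through entropies of the binned joint table.
bf_mutual_information <- function(x, y, bins) {
  ef <- function(v) ceiling(rank(v, ties.method = "first") * bins / length(v))
  bx <- ef(x)
  by <- ef(y)
  ent <- function(tab) {
    p <- tab / sum(tab)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ent(table(bx)) + ent(table(by)) - ent(table(bx, by))
}

# One-sided permutation test on the Spearman correlation, shuffling y within
# groups.
perm_spearman <- function(x, y, groups = NULL, nPerm = 999,
                          alternative = c("greater", "less"), seed = 11) {
  alternative <- match.arg(alternative)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  idx <- if (is.null(groups)) list(seq_along(y)) else split(seq_along(y), groups)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    yp <- y
    for (ii in idx) yp[ii] <- yp[ii][sample.int(length(ii))]
    rb <- suppressWarnings(cor(x, yp, method = "spearman"))
    ok <- if (alternative == "greater") rb >= rho else rb <= rho
    if (ok) hits <- hits + 1L
  }
  list(rho = rho, pValue = (1 + hits) / (1 + nPerm))
}

# Construct an EvolutionRecord directly (for table-assembly tests).
make_record <- function(generations, meanEta, exprVariance = NULL,
                        mode = "selection", geneMask = NULL) {
  n <- ncol(meanEta)
  G <- length(generations)
  if (is.null(exprVariance)) exprVariance <- matrix(1, G, n)
  if (is.null(geneMask)) geneMask <- rep(TRUE, n)
  new("EvolutionRecord",
    generations = as.integer(generations),
    meanExpression = matrix(50, G, n), exprVariance = exprVariance,
    meanEta = meanEta, medianEta = meanEta,
    meanFitness = rep(0.5, G), mode = mode, sOpt = rep(50, n),
    geneMask = geneMask, clampFraction = 0, seed = 1L
  )
}

# A ring network whose deterministic fixed point is exactly 50 for every
# gene: single regulator per gene with weight 0.6 (20 + 0.6 * 50 = 50).
ring_graph <- function(n = 8, w = 0.6) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, if (i == 1) n else i - 1] <- w
  weightedDigraph(W)
}

# A two-gene mutual repressor that oscillates between (20, 20) and (0, 0).
oscillating_graph <- function() {
  weightedDigraph(matrix(c(0, -3, -3, 0), 2, 2))
}
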