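# Outcome statistics: expression variance, relative variance change,
# gene-level selective pressure, mutual information with permutation tests,
# and assembly of the model-ready gene table.

#' Per-gene expression variance across a population
#'
#' Sample variance (denominator N - 1) of each gene's expression level across
#' individuals.
#'
#' @param states `N x n` matrix of expression phenotypes (one row per
#'   individual; N >= 2).
#' @return Length-n numeric vector of variances.
#' @examples
#' expressionVariance(rbind(c(10, 1), c(20, 1))) # c(50, 0)
#' @export
expressionVariance <- function(states) {
  states <- as.matrix(states)
  if (nrow(states) < 2L)
    stop("need at least 2 individuals")
  apply(states, 2L, var)
}

#' Relative change of expression variance between first and last generation
#'
#' `(varFirst - varLast) / (varFirst + varLast)`, in \[-1, 1\]; positive
#' values mean the variance was reduced. Vectorized; a pair with zero sum is
#' undefined and yields `NA` with a warning.
#'
#' @param varFirst,varLast Nonnegative variances (recycled to a common
#'   length).
#' @return Numeric vector in \[-1, 1\] (or `NA`).
#' @examples
#' relativeVarianceChange(100, 25) # 0.6
#' @export
relativeVarianceChange <- function(varFirst, varLast) {
  stopifnot(all(varFirst >= 0, na.rm = TRUE),
            all(varLast >= 0, na.rm = TRUE))
  tot <- varFirst + varLast
  out <- (varFirst - varLast) / tot
  if (any(tot == 0, na.rm = TRUE)) {
    warning("variance sum is zero for some gene(s); returning NA")
    out[tot == 0] <- NA_real_
  }
  out
}

#' Gene-level selective pressure from a mean-eta trajectory
#'
#' The average change of the noise genotype relative to its starting level:
#' with `e(1)` the population mean eta at generation 1 and `e(g)` the values
#' at the subsequent sampled generations,
#' `pressure = mean_g ((e(1) - e(g)) / e(1))` over sampled generations
#' `g > 1` (the zero g = 1 term is excluded). A gene is responsive iff
#' `pressure > threshold` (strict).
#'
#' @param etaTrajectory Numeric vector of per-generation population mean eta
#'   for one gene, sampled at the recording stride, first element =
#'   generation 1 (must be positive).
#' @param threshold Responsiveness cut (default 0.5).
#' @return List with `pressure` and `responsive`.
#' @examples
#' selectivePressure(c(100, 50, 50, 50))$pressure # 0.5, not responsive
#' @export
selectivePressure <- function(etaTrajectory, threshold = 0.5) {
  e <- as.numeric(etaTrajectory)
  if (length(e) < 2L)
    stop("trajectory must cover at least 2 sampled generations")
  if (e[1L] <= 0)
    stop("starting mean eta must be positive")
  pressure <- mean((e[1L] - e[-1L]) / e[1L])
  list(pressure = pressure, responsive = pressure > threshold)
}

# Equal-frequency binning into k bins; ties broken by stable rank order.
.efBin <- function(x, k) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * k / length(x)))
}

#' Plug-in mutual information with equal-frequency binning
#'
#' Both variables are discretized into `ceiling(length(x)^(1/3))` bins under
#' `bins = "auto"` by equal-frequency binning (ties broken by stable rank
#' order), and the empirical mutual information of the joint contingency
#' table is returned in nats. `MI >= 0`, `MI(x, x)` equals the entropy of the
#' binned x, and a constant vector gives 0 with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 10.
#' @param bins Number of bins, or `"auto"`.
#' @return Nonnegative mutual information in nats.
#' @examples
#' x <- 1:8 + 2 # distinct values
#' # mutualInformation(x, x, bins = 2) == log(2)
#' @export
mutualInformation <- function(x, y, bins = "auto") {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 10L)
    stop("need at least 10 observations")
  if (identical(bins, "auto"))
    bins <- ceiling(round(length(x)^(1 / 3), 9))
  bins <- as.integer(bins)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input vector; mutual information is 0")
    return(0)
  }
  nx <- .efBin(x, bins)
  ny <- .efBin(y, bins)
  nObs <- length(x)
  joint <- tabulate((ny - 1L) * bins + nx, nbins = bins * bins) / nObs
  joint <- matrix(joint, bins, bins)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Monte Carlo permutation test for mutual information
#'
#' Shuffles `y` (within groups when `groupLabels` is supplied, e.g. within
#' each network topology), recomputes the MI, and returns
#' `p = (1 + #\{MI_perm >= MI_obs\}) / (1 + nPermutations)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param nPermutations Number of permutations (>= 100; default 10000).
#' @param seed Optional integer seed.
#' @param groupLabels Optional vector of group labels for within-group
#'   shuffling.
#' @param bins Binning passed to [mutualInformation].
#' @return List with `mi`, `pValue`, `nPermutations`, `bins`.
#' @export
miPermutationTest <- function(x, y, nPermutations = 10000, seed = NULL,
                              groupLabels = NULL, bins = "auto") {
  stopifnot(nPermutations >= 100)
  obs <- suppressWarnings(mutualInformation(x, y, bins))
  groupIdx <- if (is.null(groupLabels)) {
    list(seq_along(y))
  } else {
    split(seq_along(y), groupLabels)
  }
  withSeed(seed, {
    hits <- 0L
    for (b in seq_len(nPermutations)) {
      yp <- y
      for (ii in groupIdx) yp[ii] <- yp[ii][sample.int(length(ii))]
      if (suppressWarnings(mutualInformation(x, yp, bins)) >= obs)
        hits <- hits + 1L
    }
    list(
      mi = obs, pValue = (1 + hits) / (1 + nPermutations),
      nPermutations = as.integer(nPermutations), bins = bins
    )
  })
}

#' Assemble the per-gene outcome table
#'
#' Combines replicate [EvolutionRecord-class] runs, node strengths and the
#' establishment masks into one row per (network, analyzed gene). Replicate
#' aggregation: expression variances at the first and last recorded
#' generation are averaged across replicates; the relative variance change is
#' computed per replicate and then averaged; the selective pressure is
#' averaged across replicates FIRST and then thresholded (a gene is
#' responsive iff the replicate-mean pressure exceeds the threshold). Genes
#' whose establishment steady state sat on an expression bound
#' (`intermediate_expression = FALSE`) are excluded.
#'
#' @param records Named list: one entry per network, each a list of
#'   [EvolutionRecord-class] replicates (same mode).
#' @param strengths Named list (same names): per-network data.frame from
#'   [nodeStrengths].
#' @param masks Named list (same names): per-network logical
#'   intermediate-expression mask. Defaults to the records' own gene masks.
#' @param pressureThreshold Responsiveness cut (default 0.5).
#' @param includeFiltered Keep boundary genes (flagged FALSE) instead of
#'   dropping them? Default FALSE.
#' @return data.frame with columns `network`, `gene`, `instrength`,
#'   `outstrength`, `variance_gen1`, `variance_final`,
#'   `relative_variance_change`, `selective_pressure`, `responsive`,
#'   `intermediate_expression`, `n_replicates`.
#' @export
buildGeneTable <- function(records, strengths, masks = NULL,
                           pressureThreshold = 0.5,
                           includeFiltered = FALSE) {
  ids <- names(records)
  if (is.null(ids) || any(ids == ""))
    stop("records must be a named list (one entry per network)")
  if (!all(ids %in% names(strengths)))
    stop("network ids of records and strengths do not match")
  if (!is.null(masks) && !all(ids %in% names(masks)))
    stop("network ids of records and masks do not match")
  rows <- lapply(ids, function(id) {
    reps <- records[[id]]
    if (is(reps, "EvolutionRecord")) reps <- list(reps)
    n <- ncol(reps[[1L]]@meanExpression)
    mask <- if (is.null(masks)) reps[[1L]]@geneMask else masks[[id]]
    st <- strengths[[id]]
    if (nrow(st) != n) stop(sprintf("strengths mismatch for network %s", id))
    v1 <- sapply(reps, function(r) r@exprVariance[1L, ])
    vT <- sapply(reps, function(r) r@exprVariance[nrow(r@exprVariance), ])
    relch <- sapply(seq_along(reps), function(k) {
      suppressWarnings(relativeVarianceChange(v1[, k], vT[, k]))
    })
    pres <- sapply(reps, function(r) {
      apply(r@meanEta, 2L, function(e) {
        selectivePressure(e, pressureThreshold)$pressure
      })
    })
    meanPressure <- rowMeans(pres)
    df <- data.frame(
      network = id,
      gene = seq_len(n),
      instrength = st$instrength,
      outstrength = st$outstrength,
      variance_gen1 = rowMeans(v1),
      variance_final = rowMeans(vT),
      relative_variance_change = rowMeans(relch),
      selective_pressure = meanPressure,
      responsive = meanPressure > pressureThreshold,
      intermediate_expression = mask,
      n_replicates = length(reps)
    )
    if (!includeFiltered) df <- df[df$intermediate_expression, , drop = FALSE]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the gene table with a stable column order
#'
#' @param geneTable Output of [buildGeneTable].
#' @param path File path (TSV).
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(geneTable, path) {
  cols <- c(
    "network", "gene", "instrength", "outstrength", "variance_gen1",
    "variance_final", "relative_variance_change", "selective_pressure",
    "responsive", "intermediate_expression", "n_replicates"
  )
  write.table(geneTable[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
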