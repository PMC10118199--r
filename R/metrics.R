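# Node- and graph-level network metrics and the PCA synthetic axes.

#' Node instrength and outstrength
#'
#' `instrength(i) = sum_j |w_ij|` (how strongly a gene is regulated) and
#' `outstrength(j) = sum_i |w_ij|` (how strongly it regulates others). Total
#' instrength equals total outstrength (both sum all |w|).
#'
#' @param graph A [WeightedDigraph-class].
#' @return data.frame with columns `gene` (1-based), `instrength`,
#'   `outstrength`.
#' @examples
#' g <- generateTopology("ER", nGenes = 10, density = 0.15, seed = 1)
#' nodeStrengths(g)
#' @export
nodeStrengths <- function(graph) {
  W <- abs(graph@weights)
  data.frame(
    gene = seq_len(nrow(W)),
    instrength = rowSums(W),
    outstrength = colSums(W)
  )
}

# igraph object of the unweighted directed edge set (edge iff w != 0),
# following the convention that W[i, j] != 0 is an edge j -> i.
.asIgraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(t(graph@weights != 0) * 1,
                                      mode = "directed")
}

# Freeman-style centralization of a normalized score vector in [0, 1]:
# sum over nodes of (max - score), divided by the star-graph maximum (n - 1).
.centralization <- function(score, n) {
  sum(max(score) - score) / (n - 1)
}

#' Graph-level topology metrics
#'
#' Twelve descriptors of the unweighted directed edge set (edge iff weight is
#' nonzero): `diameter` and `mean_path_distance` (directed shortest paths;
#' unreachable ordered pairs are excluded from both, the igraph convention),
#' Freeman centralization of indegree, outdegree and betweenness (directed),
#' a closeness centralization computed from normalized harmonic out-closeness
#' (harmonic scores handle unreachable pairs gracefully; the star-graph
#' normalization `sum(max - x)/(n-1)` is used), `average_degree` (2E/n),
#' `average_indegree` and `average_outdegree` (E/n), plus three configurable
#' extras, by default `reciprocity`, the `global_clustering` coefficient of
#' the undirected skeleton and `mean_betweenness`.
#'
#' @param graph A [WeightedDigraph-class] with a connected skeleton.
#' @param extras Named list of extra metric functions taking an igraph
#'   object; `NULL` keeps the defaults.
#' @return One-row data.frame of metrics.
#' @export
graphMetrics <- function(graph, extras = NULL) {
  if (!.skeletonConnected(graph@weights))
    stop("graph skeleton must be connected")
  g <- .asIgraph(graph)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  harm <- igraph::harmonic_centrality(g, mode = "out", normalized = TRUE)
  if (is.null(extras)) {
    extras <- list(
      reciprocity = function(g) igraph::reciprocity(g),
      global_clustering = function(g) {
        cc <- igraph::transitivity(igraph::as_undirected(g, mode = "collapse"),
                                   type = "global")
        if (is.nan(cc)) 0 else cc
      },
      mean_betweenness = function(g) {
        mean(igraph::betweenness(g, directed = TRUE))
      }
    )
  }
  base <- data.frame(
    diameter = igraph::diameter(g, directed = TRUE, unconnected = TRUE),
    mean_path_distance = igraph::mean_distance(g, directed = TRUE,
                                               unconnected = TRUE),
    indegree_centralization =
      igraph::centr_degree(g, mode = "in", loops = FALSE)$centralization,
    outdegree_centralization =
      igraph::centr_degree(g, mode = "out", loops = FALSE)$centralization,
    closeness_centralization = .centralization(harm, n),
    betweenness_centralization =
      igraph::centr_betw(g, directed = TRUE)$centralization,
    average_degree = 2 * e / n,
    average_indegree = e / n,
    average_outdegree = e / n
  )
  for (nm in names(extras)) base[[nm]] <- extras[[nm]](g)
  base
}

#' Synthetic topology axes from a PCA of graph-level metrics
#'
#' Standardizes the metric columns to zero mean and unit variance
#' (correlation-matrix PCA; the metrics have incommensurate scales), drops
#' zero-variance columns with a warning, and returns the first two principal
#' components as synthetic explanatory variables. Signs are oriented so that
#' `diameter` loads positively on PC1 and `average_degree` positively on PC2,
#' so PC1 reads as "synthetic diameter and centralization" and PC2 as
#' "synthetic average degree".
#'
#' @param metricsTable data.frame with one row per network; non-numeric
#'   columns (e.g. a network id) are carried through to the scores.
#' @return List with `scores` (data.frame: id columns + `PC1`, `PC2`),
#'   `loadings` (metrics x 2 matrix) and `explainedVariance` (fraction of
#'   variance per component, all components).
#' @export
syntheticAxes <- function(metricsTable) {
  metricsTable <- as.data.frame(metricsTable)
  if (nrow(metricsTable) < 3L)
    stop("need at least 3 networks for the synthetic axes")
  isNum <- vapply(metricsTable, is.numeric, logical(1))
  X <- as.matrix(metricsTable[, isNum, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf(
      "dropping zero-variance metric(s): %s",
      paste(colnames(X)[sds == 0], collapse = ", ")
    ))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2L)
    stop("fewer than 2 varying metrics: no axes can be computed")
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  rot <- p$rotation[, 1:2, drop = FALSE]
  scores <- p$x[, 1:2, drop = FALSE]
  flip <- c(1, 1)
  if ("diameter" %in% rownames(rot) && rot["diameter", 1L] < 0)
    flip[1L] <- -1
  if ("average_degree" %in% rownames(rot) && rot["average_degree", 2L] < 0)
    flip[2L] <- -1
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- sweep(scores, 2L, flip, `*`)
  colnames(rot) <- colnames(scores) <- c("PC1", "PC2")
  out <- cbind(
    metricsTable[, !isNum, drop = FALSE],
    as.data.frame(scores)
  )
  list(
    scores = out,
    loadings = rot,
    explainedVariance = p$sdev^2 / sum(p$sdev^2)
  )
}
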