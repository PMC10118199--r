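# Generation and serialization of weighted directed network topologies.

#' Generate a random weighted directed regulatory network
#'
#' Draws a directed topology of `nGenes` genes at density `density` under one
#' of three models and assigns i.i.d. Uniform(`weightLow`, `weightHigh`)
#' regulatory strengths (exact zeros are redrawn so that "edge iff nonzero
#' weight" stays well defined). Density of a directed graph without self-loops
#' is edges / (n (n-1)); the directed edge count is `round(density * n *
#' (n-1))` for every model, so ER, BA and WS draws of the same size and
#' density are edge-count matched. There is no autoregulation, and only
#' graphs whose undirected skeleton is connected are returned (rejection
#' sampling with at most `maxTries` attempts).
#'
#' `"ER"` samples the directed edge set uniformly. `"BA"`
#' (preferential-attachment, heavy-tailed degrees) and `"WS"` (rewired ring
#' lattice, small-world) are natively undirected constructions: the
#' undirected skeleton is generated with the classic constructor tuned to the
#' edge-count target (attachment parameter `round(m/(n-1))`; ring neighbours
#' `round(m/n)` with rewiring probability `wsRewire`), adjusted to the exact
#' target by adding/removing edges that preserve connectivity, and each
#' undirected edge is then oriented uniformly at random to a single
#' direction.
#'
#' @param model `"ER"`, `"BA"` or `"WS"`.
#' @param nGenes Number of genes (>= 2).
#' @param density Directed edge density in (0, 1).
#' @param weightLow,weightHigh Weight range (default -3, 3).
#' @param seed Integer seed; same inputs give a bitwise-identical matrix.
#' @param wsRewire Watts-Strogatz rewiring probability (default 0.1).
#' @param maxTries Rejection-sampling cap before erroring (default 1000).
#' @return A [WeightedDigraph-class].
#' @examples
#' g <- generateTopology("ER", nGenes = 40, density = 0.05, seed = 1)
#' sum(weightMatrix(g) != 0) # 78 directed edges
#' @export
generateTopology <- function(model = c("ER", "BA", "WS"), nGenes = 40,
                             density = 0.05, weightLow = -3, weightHigh = 3,
                             seed = NULL, wsRewire = 0.1, maxTries = 1000) {
  model <- match.arg(model)
  n <- as.integer(nGenes)
  stopifnot(n >= 2L, density > 0, density < 1, weightLow < weightHigh)
  m <- as.integer(round(density * n * (n - 1)))
  if (m < n - 1L)
    stop(sprintf(
      "density %.4g too low: %d directed edges cannot connect %d nodes",
      density, m, n
    ))
  withSeed(seed, {
    edges <- NULL
    for (try in seq_len(maxTries)) {
      cand <- switch(model,
        ER = .erDirectedEdges(n, m),
        BA = .orientEdges(.baSkeleton(n, m)),
        WS = .orientEdges(.wsSkeleton(n, m, wsRewire))
      )
      if (!is.null(cand) && .edgesConnected(cand, n)) {
        edges <- cand
        break
      }
    }
    if (is.null(edges))
      stop(sprintf("no connected %s graph found in %d tries", model, maxTries))
    w <- runif(nrow(edges), weightLow, weightHigh)
    while (any(w == 0)) # probability-zero event, kept exact
      w[w == 0] <- runif(sum(w == 0), weightLow, weightHigh)
    W <- matrix(0, n, n)
    # edge (from j, to i) means gene j regulates gene i: W[i, j]
    W[cbind(edges[, 2], edges[, 1])] <- w
    new("WeightedDigraph",
      nGenes = n, weights = W, topologyModel = model,
      seed = as.integer(if (is.null(seed)) NA else seed),
      weightRange = c(weightLow, weightHigh)
    )
  })
}

# m distinct ordered pairs without self-loops, as a 2-column (from, to) matrix
.erDirectedEdges <- function(n, m) {
  g <- igraph::sample_gnm(n, m, directed = TRUE)
  igraph::as_edgelist(g, names = FALSE)
}

# Undirected skeleton with exactly m edges from preferential attachment
.baSkeleton <- function(n, m) {
  mPA <- max(1L, as.integer(round(m / (n - 1))))
  g <- igraph::sample_pa(n, m = mPA, directed = FALSE)
  g <- igraph::simplify(g)
  .adjustEdgeCount(g, m)
}

# Undirected skeleton with exactly m edges from a rewired ring lattice
.wsSkeleton <- function(n, m, p) {
  nei <- max(1L, as.integer(round(m / n)))
  g <- igraph::sample_smallworld(1, n, nei = nei, p = p)
  g <- igraph::simplify(g)
  .adjustEdgeCount(g, m)
}

# Add random absent pairs / delete random connectivity-preserving edges until
# the undirected graph has exactly m edges. Returns NULL on failure (caller
# retries with fresh randomness).
.adjustEdgeCount <- function(g, m) {
  n <- igraph::vcount(g)
  guard <- 0L
  while (igraph::ecount(g) < m) {
    cand <- sample.int(n, 2)
    if (cand[1] != cand[2] && !igraph::are_adjacent(g, cand[1], cand[2]))
      g <- igraph::add_edges(g, cand)
    guard <- guard + 1L
    if (guard > 100L * m) return(NULL)
  }
  guard <- 0L
  while (igraph::ecount(g) > m) {
    e <- sample.int(igraph::ecount(g), 1)
    g2 <- igraph::delete_edges(g, e)
    if (igraph::is_connected(g2)) g <- g2
    guard <- guard + 1L
    if (guard > 100L * m) return(NULL)
  }
  g
}

# Orient each undirected edge uniformly at random to a single direction
.orientEdges <- function(g) {
  if (is.null(g)) return(NULL)
  el <- igraph::as_edgelist(g, names = FALSE)
  flip <- runif(nrow(el)) < 0.5
  el[flip, ] <- el[flip, 2:1, drop = FALSE]
  el
}

.edgesConnected <- function(edges, n) {
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::is_connected(g, mode = "weak")
}

#' Write / read a weighted edge list
#'
#' Tab-separated columns `source`, `target`, `weight` with 0-based node ids;
#' `source` is the regulator and `target` the regulated gene. Weights are
#' written with 17 significant digits so a round trip is lossless.
#'
#' @param graph A [WeightedDigraph-class].
#' @param path File path.
#' @return `writeEdgeList` returns `path` invisibly; `readEdgeList` returns a
#'   [WeightedDigraph-class].
#' @examples
#' g <- generateTopology("ER", nGenes = 10, density = 0.15, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeEdgeList(g, f)
#' identical(weightMatrix(readEdgeList(f)), weightMatrix(g))
#' @export
writeEdgeList <- function(graph, path) {
  W <- graph@weights
  idx <- which(W != 0, arr.ind = TRUE)
  df <- data.frame(
    source = idx[, 2] - 1L, # regulator j (column index)
    target = idx[, 1] - 1L, # regulated gene i (row index)
    weight = sprintf("%.17g", W[idx])
  )
  df <- df[order(df$source, df$target), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @param nGenes Optional node count; defaults to 1 + the largest node id.
#' @export
readEdgeList <- function(path, nGenes = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "integer", "numeric"))
  n <- if (is.null(nGenes)) max(df$source, df$target) + 1L else
    as.integer(nGenes)
  W <- matrix(0, n, n)
  W[cbind(df$target + 1L, df$source + 1L)] <- df$weight
  weightedDigraph(W)
}

#' Write / read a square adjacency (weight) matrix
#'
#' Plain TSV of the full `n x n` weight matrix (no headers), 17 significant
#' digits; the round trip is lossless.
#'
#' @param graph A [WeightedDigraph-class].
#' @param path File path.
#' @return `writeAdjacencyMatrix` returns `path` invisibly;
#'   `readAdjacencyMatrix` returns a [WeightedDigraph-class].
#' @export
writeAdjacencyMatrix <- function(graph, path) {
  W <- graph@weights
  txt <- apply(W, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname writeAdjacencyMatrix
#' @export
readAdjacencyMatrix <- function(path) {
  W <- as.matrix(read.table(path, header = FALSE, sep = "\t"))
  dimnames(W) <- NULL
  weightedDigraph(W)
}
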