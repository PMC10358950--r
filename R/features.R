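#' Per-node egonet feature table
#'
#' Computes, for every node of a simple undirected graph, the seven
#' NetSimile-style structural features used to characterize venation:
#' \describe{
#'   \item{degree}{number of neighbors.}
#'   \item{clustering}{local clustering coefficient, 2 t / (d (d - 1)); 0
#'     when degree < 2.}
#'   \item{mean_neighbor_degree}{mean degree over the node's neighbors (0 for
#'     an isolated node).}
#'   \item{mean_neighbor_clustering}{mean clustering over the neighbors.}
#'   \item{egonet_edges}{edges of the subgraph induced on the ego together
#'     with its neighbors (the one-hop egonet, ego included).}
#'   \item{egonet_outgoing_edges}{edges with exactly one endpoint inside the
#'     egonet.}
#'   \item{egonet_neighbors}{distinct nodes outside the egonet adjacent to at
#'     least one egonet member.}
#' }
#'
#' @param x a \code{\linkS4class{VeinGraph}}, an \pkg{igraph} object, or a
#'   two-column edge matrix (with \code{nNodes} giving the node count).
#' @param ... passed to methods; edge-matrix method takes \code{nNodes}.
#' @return data.frame with column \code{node} and the seven feature columns.
#' @export
#' @rdname computeNodeFeatures
setMethod("computeNodeFeatures", "VeinGraph", function(x, ...) {
  nodeFeaturesCore(cbind(x@edges$from, x@edges$to), nNodes(x))
})

#' @rdname computeNodeFeatures
setMethod("computeNodeFeatures", "ANY", function(x, ...) {
  if (inherits(x, "igraph")) {
    if (igraph::is_directed(x) || igraph::any_multiple(x) || any(igraph::which_loop(x)))
      stop("input graph must be simple and undirected")
    return(nodeFeaturesCore(igraph::as_edgelist(x, names = FALSE), igraph::vcount(x)))
  }
  stop("unsupported input type for computeNodeFeatures")
})

#' @rdname computeNodeFeatures
setMethod("computeNodeFeatures", "matrix", function(x, nNodes, ...) {
  nodeFeaturesCore(x, nNodes)
})

nodeFeaturesCore <- function(edges, n) {
  if (n < 1) stop("graph must have at least one node")
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops not allowed in a simple graph")
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(key)) stop("parallel edges not allowed in a simple graph")
  }
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    adj <- lapply(adj, sort)
  }
  deg <- lengths(adj)
  inEgo <- logical(n)
  # triangles through each node, then clustering
  tri2 <- numeric(n)  # twice the triangle count
  for (i in seq_len(n)) {
    N <- adj[[i]]
    if (deg[i] >= 2L) {
      inEgo[N] <- TRUE
      s <- 0L
      for (u in N) s <- s + sum(inEgo[adj[[u]]])
      inEgo[N] <- FALSE
      tri2[i] <- s
    }
  }
  clust <- ifelse(deg >= 2L, tri2 / (deg * (deg - 1L)), 0)
  mnd <- vapply(seq_len(n), function(i)
    if (deg[i] == 0L) 0 else mean(deg[adj[[i]]]), numeric(1))
  mnc <- vapply(seq_len(n), function(i)
    if (deg[i] == 0L) 0 else mean(clust[adj[[i]]]), numeric(1))
  egoEdges <- integer(n); egoOut <- integer(n); egoNbr <- integer(n)
  for (i in seq_len(n)) {
    ego <- c(i, adj[[i]])
    inEgo[ego] <- TRUE
    inside <- 0L; outside <- 0L; nbrs <- integer()
    for (v in ego) {
      av <- adj[[v]]
      isIn <- inEgo[av]
      inside <- inside + sum(isIn)
      outside <- outside + sum(!isIn)
      if (any(!isIn)) nbrs <- c(nbrs, av[!isIn])
    }
    inEgo[ego] <- FALSE
    egoEdges[i] <- inside %/% 2L
    egoOut[i] <- outside
    egoNbr[i] <- length(unique(nbrs))
  }
  data.frame(node = seq_len(n), degree = as.integer(deg), clustering = clust,
             mean_neighbor_degree = mnd, mean_neighbor_clustering = mnc,
             egonet_edges = egoEdges, egonet_outgoing_edges = egoOut,
             egonet_neighbors = egoNbr)
}

#' Aggregate a node feature table into the 28-vector
#'
#' For each of the seven feature columns: mean, standard deviation, skewness
#' and kurtosis, yielding the fixed-order 28-dimensional venation descriptor.
#' Defaults are population (1/n) moments with Fisher excess kurtosis
#' (g2 = m4/m2^2 - 3); a zero-variance column gets skewness = kurtosis = 0.
#'
#' @param table data.frame from \code{\link{computeNodeFeatures}}.
#' @param sdType \code{"population"} (divide by n, default) or
#'   \code{"sample"} (divide by n - 1).
#' @param kurtosisType \code{"excess"} (default) or \code{"raw"}.
#' @return named numeric vector of length 28 in \code{\link{featureNames}}
#'   order.
#' @export
aggregateFeatures <- function(table, sdType = c("population", "sample"),
                              kurtosisType = c("excess", "raw")) {
  sdType <- match.arg(sdType)
  kurtosisType <- match.arg(kurtosisType)
  feats <- setdiff(featureColumns(), "node")
  if (!all(feats %in% names(table))) stop("table is missing feature columns")
  if (nrow(table) < 1) stop("empty feature table")
  out <- numeric(0)
  for (f in feats) {
    x <- as.numeric(table[[f]])
    n <- length(x)
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    m3 <- mean((x - mu)^3)
    m4 <- mean((x - mu)^4)
    sdv <- if (sdType == "population") sqrt(m2) else stats::sd(x)
    if (m2 > 0) {
      skew <- m3 / m2^1.5
      kurt <- m4 / m2^2 - if (kurtosisType == "excess") 3 else 0
    } else {
      skew <- 0; kurt <- 0
    }
    out <- c(out, mu, sdv, skew, kurt)
  }
  names(out) <- featureNames()
  out
}

featureColumns <- function() {
  c("node", "degree", "clustering", "mean_neighbor_degree",
    "mean_neighbor_clustering", "egonet_edges", "egonet_outgoing_edges",
    "egonet_neighbors")
}

#' Names of the 28 aggregated network features
#'
#' Stable column contract: for each of the seven node features, the four
#' aggregates in the order mean, sd, skewness, kurtosis.
#'
#' @return character vector of length 28, starting with
#'   \code{"degree_mean"}.
#' @export
featureNames <- function() {
  feats <- setdiff(featureColumns(), "node")
  aggs <- c("mean", "sd", "skewness", "kurtosis")
  as.vector(t(outer(feats, aggs, paste, sep = "_")))
}

#' One-call 28-dimensional feature vector of a graph
#'
#' @param graph a \code{\linkS4class{VeinGraph}} or \pkg{igraph} object.
#' @param ... passed to \code{\link{aggregateFeatures}}.
#' @return named numeric vector of length 28.
#' @export
featureVector <- function(graph, ...) {
  aggregateFeatures(computeNodeFeatures(graph), ...)
}
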