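# Independent oracles used across tests. These deliberately re-derive results
# by brute force or alternative routes, never by calling the code paths they
# check.

# --- brute-force egonet features (explicit set enumeration, triple loop) ----
bruteNodeFeatures <- function(edges, n) {
  adjacent <- function(a, b) {
    any((edges[, 1] == a & edges[, 2] == b) | (edges[, 1] == b & edges[, 2] == a))
  }
  neigh <- function(v) {
    out <- c()
    for (u in seq_len(n)) if (u != v && adjacent(v, u)) out <- c(out, u)
    out
  }
  deg <- sapply(seq_len(n), function(v) length(neigh(v)))
  clus <- sapply(seq_len(n), function(v) {
    N <- neigh(v)
    if (length(N) < 2) return(0)
    t <- 0
    for (i in seq_along(N)) for (j in seq_along(N))
      if (i < j && adjacent(N[i], N[j])) t <- t + 1
    2 * t / (length(N) * (length(N) - 1))
  })
  res <- data.frame(node = seq_len(n), degree = deg, clustering = clus,
                    mean_neighbor_degree = 0, mean_neighbor_clustering = 0,
                    egonet_edges = 0L, egonet_outgoing_edges = 0L,
                    egonet_neighbors = 0L)
  for (v in seq_len(n)) {
    N <- neigh(v)
    res$mean_neighbor_degree[v] <- if (length(N)) mean(deg[N]) else 0
    res$mean_neighbor_clustering[v] <- if (length(N)) mean(clus[N]) else 0
    ego <- c(v, N)
    inside <- 0L
    for (a in ego) for (b in ego) if (a < b && adjacent(a, b)) inside <- inside + 1L
    outgoing <- 0L
    ns <- c()
    for (a in ego) for (b in seq_len(n)) {
      if (!(b %in% ego) && adjacent(a, b)) {
        outgoing <- outgoing + 1L
        ns <- c(ns, b)
      }
    }
    res$egonet_edges[v] <- inside
    res$egonet_outgoing_edges[v] <- outgoing
    res$egonet_neighbors[v] <- length(unique(ns))
  }
  res
}

# random simple undirected graph as an edge matrix (Erdos-Renyi style)
randomGraphEdges <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

# --- image topology through the pixel-adjacency graph (igraph route) --------
pixelGraphTopology <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(list(components = 0L, cycleRank = 0L))
  key <- paste(idx[, 1], idx[, 2])
  id <- seq_len(n)
  names(id) <- key
  from <- integer(); to <- integer()
  for (dr in -1:1) for (dc in -1:1) {
    if (dr < 0 || (dr == 0 && dc <= 0)) next  # each unordered pair once
    nb <- paste(idx[, 1] + dr, idx[, 2] + dc)
    hit <- nb %in% key
    from <- c(from, id[hit])
    to <- c(to, id[nb[hit]])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  comps <- igraph::components(g)$no
  # cycle rank of the pixel graph exceeds the hole count when solid triangles
  # of pixels occur; thin skeletons avoid them, so E - V + C equals the
  # number of independent holes there
  list(components = comps,
       cycleRank = igraph::ecount(g) - n + comps)
}

# --- exhaustive between-class variance scan (Otsu oracle) -------------------
otsuScan <- function(gray) {
  lv <- sort(unique(as.vector(gray)))
  best <- -Inf; bestT <- lv[1]
  for (t in lv[-length(lv)]) {
    g0 <- gray[gray <= t]; g1 <- gray[gray > t]
    w0 <- length(g0) / length(gray); w1 <- 1 - w0
    v <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (v > best) { best <- v; bestT <- t }
  }
  bestT
}

# --- moments oracle ---------------------------------------------------------
momentsOracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu,
    sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# apply a homography to (x, y) points
applyHomography <- function(H, pts) {
  q <- H %*% rbind(t(pts), 1)
  cbind(q[1, ] / q[3, ], q[2, ] / q[3, ])
}

# quick synthetic sample helper used by several files
sampleFixture <- function(seed, loopiness = 0.3, nAnchors = 30L,
                          strokeWidth = 3L, imageSize = c(512L, 512L)) {
  makeGroundTruthSample(VenationSpec(nAnchors, loopiness, strokeWidth,
                                     imageSize, seed))
}
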