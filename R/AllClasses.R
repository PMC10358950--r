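#' Undirected vein network graph
#'
#' S4 container for a vein network extracted from a skeleton image (or built
#' synthetically). Nodes carry a pixel centroid (1-based \code{row}, \code{col})
#' and a kind (\code{"endpoint"}, \code{"branch"}, or \code{"passthrough"} for
#' synthetic degree-2 anchors). Edges are stored as a simple undirected view
#' (no self-loops, no parallel edges): parallel pixel paths between the same
#' node pair are recorded via \code{multiplicity}, self-loops (a path leaving
#' and re-entering the same node) in the \code{loops} slot, and node-free
#' skeleton cycles in \code{orphanCycleCount}. This bookkeeping keeps the
#' cycle rank of the simple view reconcilable with the cycle rank of the
#' underlying skeleton image.
#'
#' @slot nodes data.frame with columns \code{id}, \code{row}, \code{col},
#'   \code{kind}; ids are contiguous 1..V.
#' @slot edges data.frame with columns \code{from}, \code{to} (unordered,
#'   stored with \code{from < to}), \code{length_px} (sqrt(2)-weighted pixel
#'   path length; shortest trace for parallel paths), \code{multiplicity},
#'   and optionally \code{length_total_px} (summed length of all parallel
#'   traces).
#' @slot loops data.frame with columns \code{node}, \code{length_px}; one row
#'   per self-loop.
#' @slot orphanCycleCount integer, skeleton cycles containing no node pixel.
#'
#' @param x a \code{VeinGraph}.
#' @return \code{nNodes}/\code{nEdges} return counts of the simple view;
#'   \code{cycleRank} returns the total cycle rank including multiplicity
#'   excess, self-loops and orphan cycles; \code{nodeDegrees} the simple-view
#'   degree per node; \code{asIgraph} an \pkg{igraph} object of the simple view
#'   with node/edge attributes.
#' @export
setClass("VeinGraph", representation(
  nodes = "data.frame",
  edges = "data.frame",
  loops = "data.frame",
  orphanCycleCount = "integer"
))

setValidity("VeinGraph", function(object) {
  n <- object@nodes
  e <- object@edges
  msg <- character()
  if (!all(c("id", "row", "col", "kind") %in% names(n)))
    msg <- c(msg, "nodes must have columns id, row, col, kind")
  if (!all(c("from", "to", "length_px", "multiplicity") %in% names(e)))
    msg <- c(msg, "edges must have columns from, to, length_px, multiplicity")
  if (length(msg)) return(msg)
  if (nrow(n) > 0 && !identical(as.integer(n$id), seq_len(nrow(n))))
    msg <- c(msg, "node ids must be contiguous 1..V")
  if (!all(n$kind %in% c("endpoint", "branch", "passthrough")))
    msg <- c(msg, "unknown node kind")
  if (nrow(e) > 0) {
    if (any(e$from >= e$to)) msg <- c(msg, "edges must satisfy from < to (no self-loops in simple view)")
    if (any(!c(e$from, e$to) %in% n$id)) msg <- c(msg, "edge endpoint not a node id")
    if (anyDuplicated(e[, c("from", "to")])) msg <- c(msg, "parallel edges must be folded into multiplicity")
    if (any(e$multiplicity < 1)) msg <- c(msg, "multiplicity must be >= 1")
  }
  if (object@orphanCycleCount < 0) msg <- c(msg, "orphanCycleCount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a VeinGraph
#'
#' @param nodes data.frame with \code{id}, \code{row}, \code{col}, \code{kind}.
#' @param edges data.frame with \code{from}, \code{to}, \code{length_px},
#'   \code{multiplicity} (defaulted to 1 if absent).
#' @param loops data.frame with \code{node}, \code{length_px} (self-loops).
#' @param orphanCycles integer count of node-free cycles.
#' @return a validated \code{VeinGraph}.
#' @export
VeinGraph <- function(nodes = data.frame(id = integer(), row = numeric(),
                                         col = numeric(), kind = character()),
                      edges = data.frame(from = integer(), to = integer(),
                                         length_px = numeric(), multiplicity = integer()),
                      loops = data.frame(node = integer(), length_px = numeric()),
                      orphanCycles = 0L) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (is.null(edges$multiplicity)) edges$multiplicity <- 1L
    if (is.null(edges$length_px)) edges$length_px <- NA_real_
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
    edges$from <- as.integer(edges$from); edges$to <- as.integer(edges$to)
  }
  if (nrow(nodes) > 0) nodes$id <- as.integer(nodes$id)
  new("VeinGraph", nodes = nodes, edges = edges, loops = as.data.frame(loops),
      orphanCycleCount = as.integer(orphanCycles))
}

#' @rdname VeinGraph-class
#' @export
setMethod("nNodes", "VeinGraph", function(x) nrow(x@nodes))

#' @rdname VeinGraph-class
#' @export
setMethod("nEdges", "VeinGraph", function(x) nrow(x@edges))

#' @rdname VeinGraph-class
#' @export
setMethod("nodeTable", "VeinGraph", function(x) x@nodes)

#' @rdname VeinGraph-class
#' @export
setMethod("edgeTable", "VeinGraph", function(x) x@edges)

#' @rdname VeinGraph-class
#' @export
setMethod("selfLoopCount", "VeinGraph", function(x) nrow(x@loops))

#' @rdname VeinGraph-class
#' @export
setMethod("orphanCycleCount", "VeinGraph", function(x) x@orphanCycleCount)

#' @rdname VeinGraph-class
#' @export
setMethod("nodeDegrees", "VeinGraph", function(x) {
  d <- integer(nNodes(x))
  if (nEdges(x) > 0) {
    t1 <- tabulate(x@edges$from, nbins = nNodes(x))
    t2 <- tabulate(x@edges$to, nbins = nNodes(x))
    d <- t1 + t2
  }
  names(d) <- x@nodes$id
  d
})

#' @rdname VeinGraph-class
#' @export
setMethod("cycleRank", "VeinGraph", function(x) {
  v <- nNodes(x)
  etot <- sum(x@edges$multiplicity) + nrow(x@loops)
  comp <- if (v == 0) 0L else length(unique(graphComponents(x)))
  as.integer(etot - v + comp + x@orphanCycleCount)
})

#' @rdname VeinGraph-class
#' @export
setMethod("asIgraph", "VeinGraph", function(x, ...) {
  g <- igraph::make_empty_graph(n = nNodes(x), directed = FALSE)
  if (nNodes(x) > 0) {
    g <- igraph::set_vertex_attr(g, "kind", value = x@nodes$kind)
    g <- igraph::set_vertex_attr(g, "row", value = x@nodes$row)
    g <- igraph::set_vertex_attr(g, "col", value = x@nodes$col)
  }
  if (nEdges(x) > 0) {
    g <- igraph::add_edges(g, rbind(x@edges$from, x@edges$to))
    g <- igraph::set_edge_attr(g, "length_px", value = x@edges$length_px)
    g <- igraph::set_edge_attr(g, "multiplicity", value = x@edges$multiplicity)
  }
  g
})

setMethod("show", "VeinGraph", function(object) {
  kinds <- table(factor(object@nodes$kind, levels = c("endpoint", "branch", "passthrough")))
  cat("VeinGraph:", nNodes(object), "nodes (",
      kinds[["endpoint"]], "endpoint,", kinds[["branch"]], "branch ),",
      nEdges(object), "edges\n")
  cat("  cycle rank:", cycleRank(object),
      "| self-loops:", nrow(object@loops),
      "| orphan cycles:", object@orphanCycleCount, "\n")
})

# component id per node (simple view), internal
graphComponents <- function(x) {
  v <- nNodes(x)
  comp <- rep(0L, v)
  adj <- vector("list", v)
  if (nEdges(x) > 0) {
    for (k in seq_len(nrow(x@edges))) {
      f <- x@edges$from[k]; t <- x@edges$to[k]
      adj[[f]] <- c(adj[[f]], t); adj[[t]] <- c(adj[[t]], f)
    }
  }
  cur <- 0L
  for (i in seq_len(v)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in adj[[p]]) if (comp[q] == 0L) { comp[q] <- cur; queue <- c(queue, q) }
    }
  }
  comp
}

#' Synthetic venation specification
#'
#' Parameters of the synthetic planar-graph venation generator: the number of
#' anchor points seeding the graph, the loopiness (fraction of non-spanning-tree
#' Delaunay edges retained, the generator's analogue of the relative frequency
#' of vein loops), the stroke width used at rasterization, the image size and
#' the RNG seed.
#'
#' @slot nAnchors integer >= 3.
#' @slot loopiness numeric in [0, 1].
#' @slot strokeWidth integer >= 1 (pixels).
#' @slot imageSize integer length-2 (rows, cols).
#' @slot seed integer.
#' @export
setClass("VenationSpec", representation(
  nAnchors = "integer", loopiness = "numeric", strokeWidth = "integer",
  imageSize = "integer", seed = "integer"
))

setValidity("VenationSpec", function(object) {
  msg <- character()
  if (object@nAnchors < 3L) msg <- c(msg, "nAnchors must be >= 3")
  if (object@loopiness < 0 || object@loopiness > 1) msg <- c(msg, "loopiness must be in [0, 1]")
  if (object@strokeWidth < 1L) msg <- c(msg, "strokeWidth must be >= 1")
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    msg <- c(msg, "imageSize must be two dimensions >= 8")
  # anchors must fit with spacing > 2 * strokeWidth inside the inset margin
  inner <- object@imageSize - 4L * object@strokeWidth
  if (any(inner < 2L * object@strokeWidth))
    msg <- c(msg, "imageSize too small for the requested strokeWidth")
  if (length(msg)) msg else TRUE
})

#' Construct a VenationSpec
#'
#' @param nAnchors number of anchor points (>= 3).
#' @param loopiness fraction of extra (non-tree) Delaunay edges kept, in [0, 1].
#' @param strokeWidth stroke width in pixels at rasterization.
#' @param imageSize integer (rows, cols).
#' @param seed RNG seed.
#' @return a validated \code{VenationSpec}.
#' @export
VenationSpec <- function(nAnchors = 30L, loopiness = 0.3, strokeWidth = 3L,
                         imageSize = c(512L, 512L), seed = 1L) {
  new("VenationSpec", nAnchors = as.integer(nAnchors), loopiness = as.numeric(loopiness),
      strokeWidth = as.integer(strokeWidth), imageSize = as.integer(imageSize),
      seed = as.integer(seed))
}

setMethod("show", "VenationSpec", function(object) {
  cat(sprintf("VenationSpec: %d anchors, loopiness %.2f, stroke %d px, %dx%d, seed %d\n",
              object@nAnchors, object@loopiness, object@strokeWidth,
              object@imageSize[1], object@imageSize[2], object@seed))
})

#' Ground-truthed synthetic venation sample
#'
#' Bundles a synthetic planar vein graph, its binary rasterization, an
#' optional degraded grayscale rendering, and the generating spec.
#'
#' @slot graph the planar \code{\linkS4class{VeinGraph}} (anchors as nodes,
#'   straight-segment edges).
#' @slot binaryImage logical matrix, rasterized strokes (vein = TRUE).
#' @slot grayImage numeric matrix in [0,1] or a 0x0 matrix when no degradation
#'   was applied.
#' @slot spec the \code{\linkS4class{VenationSpec}} used.
#' @export
setClass("GroundTruthSample", representation(
  graph = "VeinGraph", binaryImage = "matrix", grayImage = "matrix",
  spec = "VenationSpec"
))

setValidity("GroundTruthSample", function(object) {
  msg <- character()
  if (!is.logical(object@binaryImage)) msg <- c(msg, "binaryImage must be logical")
  n <- object@graph@nodes
  if (nrow(n) > 0) {
    if (any(n$row < 1 | n$row > nrow(object@binaryImage) |
            n$col < 1 | n$col > ncol(object@binaryImage)))
      msg <- c(msg, "graph node coordinates outside image bounds")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruthSample", function(object) {
  cat("GroundTruthSample:", nrow(object@binaryImage), "x", ncol(object@binaryImage),
      "image;", sum(object@binaryImage), "foreground px\n")
  show(object@spec)
  show(object@graph)
})

#' Frame calibration model
#'
#' A projective rectification (3x3 homography mapping source pixel coordinates
#' to rectified coordinates) together with the physical area represented by
#' one rectified pixel.
#'
#' @slot homography 3x3 numeric matrix, nonsingular, normalized so the
#'   bottom-right entry is 1.
#' @slot areaScale cm^2 per pixel (> 0, or NA when not yet estimated).
#' @param x a \code{CalibrationModel}.
#' @export
setClass("CalibrationModel", representation(homography = "matrix", areaScale = "numeric"))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (!all(dim(object@homography) == c(3L, 3L))) msg <- c(msg, "homography must be 3x3")
  else if (abs(det(object@homography)) < 1e-12) msg <- c(msg, "homography is singular")
  if (!is.na(object@areaScale) && object@areaScale <= 0) msg <- c(msg, "areaScale must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CalibrationModel
#' @param homography 3x3 projective matrix (source -> rectified).
#' @param areaScale cm^2 per pixel, or NA.
#' @return a validated \code{CalibrationModel}.
#' @export
CalibrationModel <- function(homography = diag(3), areaScale = NA_real_) {
  h <- homography / homography[3, 3]
  new("CalibrationModel", homography = h, areaScale = as.numeric(areaScale))
}

#' @rdname CalibrationModel-class
#' @export
setMethod("homographyMatrix", "CalibrationModel", function(x) x@homography)

#' @rdname CalibrationModel-class
#' @export
setMethod("areaScale", "CalibrationModel", function(x) x@areaScale)

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel: areaScale =", object@areaScale, "cm^2/px\n")
  print(signif(object@homography, 6))
})
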