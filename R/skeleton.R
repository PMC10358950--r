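#' Topology-preserving skeletonization
#'
#' Thins a binary vein mask to 1-pixel-wide curves by sequential removal of
#' simple border pixels (Yokoi 8-connectivity number) with endpoint
#' preservation, alternating N/S/E/W border sub-passes until stable. Because
#' every individual deletion is a simple-point deletion, the number of
#' 8-connected components and the cycle rank of the foreground are preserved
#' exactly; already-thin inputs without redundant corner pixels pass through
#' unchanged.
#'
#' @param mask logical (or 0/1 numeric) matrix, vein = TRUE.
#' @return logical matrix, the skeleton.
#' @export
skeletonize <- function(mask) {
  mask <- asMask(mask)
  if (!any(mask)) {
    warning("empty mask: returning empty skeleton")
    return(mask)
  }
  cpp_thin(mask)
}

#' Magnify a skeleton 2x
#'
#' Nearest-neighbor 2x upsampling followed by re-thinning to restore 1-pixel
#' width. Used to separate branch points that sit too close together in dense
#' networks; component count and cycle rank are unchanged.
#'
#' @param skeleton logical matrix (1-px skeleton).
#' @return logical matrix of roughly doubled extent.
#' @export
magnify2x <- function(skeleton) {
  up <- skeleton[rep(seq_len(nrow(skeleton)), each = 2L),
                 rep(seq_len(ncol(skeleton)), each = 2L), drop = FALSE]
  if (!any(up)) return(up)
  cpp_thin(up)
}

# circular-neighborhood summaries for every pixel: foreground neighbor count
# and number of maximal runs of foreground in the circular 8-neighborhood
neighborhoodStats <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- sk
  shift <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  nb <- lapply(seq_len(8L), function(k) shift(NB8[k, 1], NB8[k, 2]))
  B <- Reduce(`+`, nb)
  runs <- matrix(0L, nr, nc)
  for (k in seq_len(8L)) {
    prev <- nb[[if (k == 1L) 8L else k - 1L]]
    runs <- runs + (nb[[k]] & !prev)
  }
  # all-8 neighborhood: zero transitions but one run
  runs[B == 8L] <- 1L
  list(count = B, runs = runs)
}

#' Detect endpoint and branch-point pixels of a skeleton
#'
#' A skeleton pixel is an endpoint when exactly one of its 8 neighbors is a
#' vein pixel, and a branching point when three or more of its 8 neighbors
#' are vein pixels (\code{criterion = "count"}, the default: degenerate
#' trifurcations whose two arms are mutually adjacent are still flagged,
#' and adjacent-node merging absorbs the extra flagged pixels into one
#' junction). \code{criterion = "runs"} instead requires three or more
#' maximal runs of adjacent vein pixels in the circular 8-neighborhood
#' (a crossing-number rule); it never flags interior pixels of thick
#' clusters but misses the degenerate trifurcation case.
#'
#' @param skeleton logical matrix (1-px skeleton).
#' @param criterion \code{"count"} (default) or \code{"runs"}.
#' @return list with two 2-column integer matrices (row, col):
#'   \code{endpoints} and \code{branches}.
#' @export
detectNodePixels <- function(skeleton, criterion = c("count", "runs")) {
  criterion <- match.arg(criterion)
  st <- neighborhoodStats(skeleton)
  ep <- skeleton & st$count == 1L
  bp <- if (criterion == "runs") skeleton & st$runs >= 3L else skeleton & st$count >= 3L
  bp <- bp & !ep
  list(endpoints = which(ep, arr.ind = TRUE, useNames = FALSE),
       branches = which(bp, arr.ind = TRUE, useNames = FALSE))
}

#' Merge adjacent node pixels into nodes
#'
#' Eight-connected components of the union of endpoint and branch pixels
#' collapse to one node each: centroid = mean pixel coordinate, kind = branch
#' if any member pixel is a branch pixel, ids assigned in raster-scan order of
#' each component's first pixel.
#'
#' @param nodePixels list with \code{endpoints} and \code{branches} matrices,
#'   as returned by \code{\link{detectNodePixels}}.
#' @param dim integer (rows, cols) of the skeleton image.
#' @return list with \code{nodes} (data.frame id, row, col, kind) and
#'   \code{labels} (integer matrix mapping node pixels to node ids, 0
#'   elsewhere).
#' @export
mergeAdjacentNodes <- function(nodePixels, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[nodePixels$endpoints] <- TRUE
  m[nodePixels$branches] <- TRUE
  lab <- cpp_label8(m)
  k <- max(lab)
  if (k == 0L) {
    return(list(nodes = data.frame(id = integer(), row = numeric(),
                                   col = numeric(), kind = character()),
                labels = lab))
  }
  idx <- which(m)
  ids <- lab[idx]
  rows <- (idx - 1L) %% dim[1] + 1L
  cols <- (idx - 1L) %/% dim[1] + 1L
  isBranch <- logical(k)
  if (nrow(nodePixels$branches)) {
    bids <- lab[nodePixels$branches]
    isBranch[unique(bids)] <- TRUE
  }
  nodes <- data.frame(
    id = seq_len(k),
    row = as.numeric(tapply(rows, ids, mean)[as.character(seq_len(k))]),
    col = as.numeric(tapply(cols, ids, mean)[as.character(seq_len(k))]),
    kind = ifelse(isBranch, "branch", "endpoint"))
  list(nodes = nodes, labels = lab)
}

# ordered pixel walk of one segment component, using a padded lookup matrix
# locPad with the segment's local pixel indices already written; returns
# list(order = index vector into (rows, cols), cyclic = logical)
orderSegment <- function(rows, cols, locPad) {
  n <- length(rows)
  if (n == 1L) return(list(order = 1L, cyclic = FALSE))
  degIn <- integer(n)
  for (k in seq_len(8L))
    degIn <- degIn + (locPad[cbind(rows + 1L + NB8[k, 1], cols + 1L + NB8[k, 2])] > 0L)
  ends <- which(degIn <= 1L)
  start <- if (length(ends)) ends[order(rows[ends], cols[ends])][1]
           else order(rows, cols)[1]
  visited <- logical(n)
  ord <- integer(n)
  cur <- start; visited[cur] <- TRUE; ord[1] <- cur
  for (step in seq_len(n - 1L)) {
    nxt <- 0L
    for (k in seq_len(8L)) {
      j <- locPad[rows[cur] + 1L + NB8[k, 1], cols[cur] + 1L + NB8[k, 2]]
      if (j > 0L && !visited[j]) { nxt <- j; break }
    }
    if (nxt == 0L) break
    visited[nxt] <- TRUE
    ord[step + 1L] <- nxt
    cur <- nxt
  }
  ord <- ord[ord != 0L]
  list(order = ord, cyclic = length(ends) == 0L)
}

# collapse attachment-token runs: merge consecutive tokens of the same
# component at adjacent walk positions; returns collapsed (pos, comp, dist)
# plus the original position of each kept run's last member (for wrap checks)
collapseTokens <- function(tpos, tcomp, tdist) {
  kp <- integer(); kc <- integer(); kd <- numeric(); klast <- integer()
  for (i in seq_along(tpos)) {
    nk <- length(kp)
    if (nk > 0L && tcomp[i] == kc[nk] && tpos[i] - klast[nk] <= 1L) {
      kd[nk] <- min(kd[nk], tdist[i])
      klast[nk] <- tpos[i]
    } else {
      kp <- c(kp, tpos[i]); kc <- c(kc, tcomp[i]); kd <- c(kd, tdist[i])
      klast <- c(klast, tpos[i])
    }
  }
  list(pos = kp, comp = kc, dist = kd, lastPos = klast)
}

#' Trace edges between nodes along a skeleton
#'
#' Decomposes the non-node skeleton pixels into 8-connected path segments and
#' walks each one in deterministic order (neighbors probed N, NE, E, SE, S,
#' SW, W, NW; walks start at the raster-smallest segment end), so every
#' skeleton pixel is consumed by exactly one walk. Wherever a walked pixel
#' touches a node component the segment is split: consecutive splits yield
#' edges carrying the sqrt(2)-weighted path length. A segment re-entering the
#' node it left becomes a self-loop; repeated node pairs fold into edge
#' multiplicity; segments touching no node (node-free cycles) are counted as
#' orphan cycles.
#'
#' @param skeleton logical matrix (1-px skeleton).
#' @param nodeInfo list from \code{\link{mergeAdjacentNodes}}.
#' @return a \code{\linkS4class{VeinGraph}} (possibly disconnected; see
#'   \code{\link{largestComponent}}).
#' @export
traceEdges <- function(skeleton, nodeInfo) {
  lab <- nodeInfo$labels
  nodes <- nodeInfo$nodes
  segMask <- skeleton & lab == 0L
  segLab <- cpp_label8(segMask)
  nseg <- max(segLab)
  nr <- nrow(skeleton)
  edgeFrom <- integer(); edgeTo <- integer(); edgeLen <- numeric()
  orphans <- 0L
  padLab <- matrix(0L, nr + 2L, ncol(skeleton) + 2L)
  padLab[2:(nr + 1L), 2:(ncol(skeleton) + 1L)] <- lab
  adjComps <- function(r, c) {
    # node components adjacent to pixel (r, c), in fixed neighbor order,
    # with the step distance to the touching node pixel
    out <- integer(); dd <- numeric()
    for (k in seq_len(8L)) {
      v <- padLab[r + 1L + NB8[k, 1], c + 1L + NB8[k, 2]]
      if (v > 0L && !(v %in% out)) {
        out <- c(out, v)
        dd <- c(dd, if (NB8[k, 1] != 0L && NB8[k, 2] != 0L) sqrt(2) else 1)
      } else if (v > 0L) {
        i <- match(v, out)
        dd[i] <- min(dd[i], if (NB8[k, 1] != 0L && NB8[k, 2] != 0L) sqrt(2) else 1)
      }
    }
    list(comp = out, dist = dd)
  }
  if (nseg > 0) {
    segIdx <- which(segMask)
    segId <- segLab[segIdx]
    segRows <- (segIdx - 1L) %% nr + 1L
    segCols <- (segIdx - 1L) %/% nr + 1L
    bySeg <- split(seq_along(segIdx), segId)
    locPad <- matrix(0L, nr + 2L, ncol(skeleton) + 2L)
    for (s in seq_len(nseg)) {
      ii <- bySeg[[as.character(s)]]
      remaining <- seq_along(ii)
      while (length(remaining)) {
      rows <- segRows[ii][remaining]; cols <- segCols[ii][remaining]
      locPad[cbind(rows + 1L, cols + 1L)] <- seq_along(rows)
      ow <- orderSegment(rows, cols, locPad)
      locPad[cbind(rows + 1L, cols + 1L)] <- 0L
      ord <- ow$order
      # a segment with an internal (undetected) branching yields several
      # walks; leftover pixels are traced by further passes
      remaining <- remaining[-ord]
      rows <- rows[ord]; cols <- cols[ord]
      m <- length(rows)
      # cumulative sqrt(2)-weighted length along the walk
      stepLen <- if (m > 1) sqrt(diff(rows)^2 + diff(cols)^2) else numeric()
      cum <- c(0, cumsum(stepLen))
      # attachment tokens: (walk position, node component, attach distance)
      tpos <- integer(); tcomp <- integer(); tdist <- numeric()
      for (i in seq_len(m)) {
        ac <- adjComps(rows[i], cols[i])
        for (j in seq_along(ac$comp)) {
          tpos <- c(tpos, i); tcomp <- c(tcomp, ac$comp[j]); tdist <- c(tdist, ac$dist[j])
        }
      }
      if (length(tcomp) == 0L) {
        orphans <- orphans + 1L  # node-free cycle (or stray isolated pixel)
        next
      }
      if (ow$cyclic && tpos[1] > 1L) {
        # rotate walk so it starts at the first attached pixel
        first <- tpos[1]
        rot <- c(first:m, seq_len(first - 1L))
        rows <- rows[rot]; cols <- cols[rot]
        stepLen <- sqrt(diff(rows)^2 + diff(cols)^2)
        cum <- c(0, cumsum(stepLen))
        tpos <- ((tpos - first) %% m) + 1L
        o <- order(tpos)
        tpos <- tpos[o]; tcomp <- tcomp[o]; tdist <- tdist[o]
      }
      tk <- collapseTokens(tpos, tcomp, tdist)
      k <- length(tk$comp)
      if (ow$cyclic) {
        cycLen <- cum[m] + sqrt((rows[m] - rows[1])^2 + (cols[m] - cols[1])^2)
        # wrap collapse: same component touching across the walk origin
        if (k >= 2L && tk$comp[k] == tk$comp[1] && (tk$pos[1] + m - tk$lastPos[k]) <= 1L) {
          tk$dist[1] <- min(tk$dist[1], tk$dist[k])
          tk <- lapply(tk, function(v) v[-k])
          k <- k - 1L
        }
        if (k == 1L) {
          edgeFrom <- c(edgeFrom, tk$comp[1]); edgeTo <- c(edgeTo, tk$comp[1])
          edgeLen <- c(edgeLen, cycLen + 2 * tk$dist[1])
        } else {
          for (i in seq_len(k)) {
            j <- if (i == k) 1L else i + 1L
            pl <- if (i == k) cycLen - (cum[tk$pos[i]] - cum[tk$pos[1]])
                  else cum[tk$pos[j]] - cum[tk$pos[i]]
            edgeFrom <- c(edgeFrom, tk$comp[i]); edgeTo <- c(edgeTo, tk$comp[j])
            edgeLen <- c(edgeLen, pl + tk$dist[i] + tk$dist[j])
          }
        }
      } else {
        if (k == 1L) next  # stub attached at a single spot: no traversable edge
        for (i in seq_len(k - 1L)) {
          edgeFrom <- c(edgeFrom, tk$comp[i]); edgeTo <- c(edgeTo, tk$comp[i + 1L])
          edgeLen <- c(edgeLen, cum[tk$pos[i + 1L]] - cum[tk$pos[i]] +
                         tk$dist[i] + tk$dist[i + 1L])
        }
      }
      }
    }
  }
  self <- edgeFrom == edgeTo
  loops <- data.frame(node = edgeFrom[self], length_px = edgeLen[self])
  f <- pmin(edgeFrom[!self], edgeTo[!self])
  t2 <- pmax(edgeFrom[!self], edgeTo[!self])
  l2 <- edgeLen[!self]
  if (length(f)) {
    key <- paste(f, t2)
    lenAgg <- tapply(l2, key, min)
    lenTot <- tapply(l2, key, sum)
    cnt <- table(key)
    ord <- names(lenAgg)
    parts <- do.call(rbind, strsplit(ord, " "))
    edges <- data.frame(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]),
                        length_px = as.numeric(lenAgg),
                        multiplicity = as.integer(cnt[ord]),
                        length_total_px = as.numeric(lenTot[ord]))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        length_px = numeric(), multiplicity = integer(),
                        length_total_px = numeric())
  }
  if (nrow(nodes) == 0L && orphans > 0L)
    warning("skeleton contains only node-free cycles: empty graph")
  VeinGraph(nodes, edges, loops, orphans)
}

#' Largest connected component of a vein graph
#'
#' Keeps the component with the most nodes; ties broken by most (simple)
#' edges, then by lowest minimum node id. Node ids are re-indexed contiguously
#' (preserving relative order); self-loops on discarded nodes and their edges
#' are dropped, orphan-cycle bookkeeping is kept.
#'
#' @param graph a \code{\linkS4class{VeinGraph}}.
#' @return a \code{\linkS4class{VeinGraph}}.
#' @export
largestComponent <- function(graph) {
  if (nNodes(graph) == 0) return(graph)
  comp <- graphComponents(graph)
  tab <- table(comp)
  sizes <- as.integer(tab)
  compIds <- as.integer(names(tab))
  ecount <- vapply(compIds, function(ci)
    sum(comp[graph@edges$from] == ci), integer(1))
  minId <- vapply(compIds, function(ci) min(which(comp == ci)), integer(1))
  ord <- order(-sizes, -ecount, minId)
  winner <- compIds[ord[1]]
  keep <- which(comp == winner)
  remap <- integer(nNodes(graph)); remap[keep] <- seq_along(keep)
  nodes <- graph@nodes[keep, , drop = FALSE]
  nodes$id <- seq_along(keep)
  rownames(nodes) <- NULL
  e <- graph@edges[graph@edges$from %in% keep, , drop = FALSE]
  e$from <- remap[e$from]; e$to <- remap[e$to]
  rownames(e) <- NULL
  lo <- graph@loops[graph@loops$node %in% keep, , drop = FALSE]
  lo$node <- remap[lo$node]
  VeinGraph(nodes, e, lo, graph@orphanCycleCount)
}

#' Remove skeleton-scale artifacts from a traced vein graph
#'
#' Pixel-level skeleton tracing leaves three artifact classes that have no
#' counterpart in the underlying vein structure: short spurs (endpoint tails
#' created by thinning at junctions), split junctions (a single high-degree
#' intersection thinned into two or more branch points a few pixels apart),
#' and tiny self-loops (stroke-union pinches). This pass removes them in
#' order, to a fixed point: self-loops shorter than \code{loopLength} are
#' dropped; endpoint-terminated edges shorter than \code{spurLength} whose
#' other end is a branch are pruned; branch-branch edges shorter than
#' \code{mergeLength} are contracted (nodes merged at their mean position);
#' degree-2 nodes arising along the way are spliced out. All thresholds are
#' in pixels and must sit below the smallest genuine structure of the imaged
#' network (for the synthetic generator, the enforced anchor spacing of four
#' stroke widths); set any threshold to 0 to disable that rule.
#'
#' @param graph a \code{\linkS4class{VeinGraph}}.
#' @param spurLength prune endpoint edges shorter than this (default 8).
#' @param mergeLength contract branch-branch node pairs nearer than this
#'   (default 16).
#' @param loopLength drop self-loops shorter than this (default 16).
#' @return a cleaned \code{\linkS4class{VeinGraph}}.
#' @export
cleanGraph <- function(graph, spurLength = 8, mergeLength = 16, loopLength = 16) {
  v <- nNodes(graph)
  if (v == 0) return(graph)
  ed <- graph@edges
  rep_ <- if (nrow(ed)) rep(seq_len(nrow(ed)), ed$multiplicity) else integer()
  e <- data.frame(from = ed$from[rep_], to = ed$to[rep_], len = ed$length_px[rep_])
  if (!is.null(ed$length_total_px) && nrow(e)) {
    # distribute the non-minimal parallel length over the extra copies
    first <- !duplicated(rep_)
    extra <- (ed$length_total_px - ed$length_px)[rep_] / pmax(ed$multiplicity - 1L, 1L)[rep_]
    e$len[!first] <- extra[!first]
  }
  if (nrow(graph@loops))
    e <- rbind(e, data.frame(from = graph@loops$node, to = graph@loops$node,
                             len = graph@loops$length_px))
  nodes <- graph@nodes
  alive <- rep(TRUE, v)
  repeat {
    isLoop <- e$from == e$to
    deg <- tabulate(c(e$from[!isLoop], e$to[!isLoop]), nbins = v) +
           2L * tabulate(e$from[isLoop], nbins = v)
    # 1. pinch self-loops
    drop <- which(isLoop & e$len < loopLength)
    if (length(drop)) { e <- e[-drop[1], , drop = FALSE]; next }
    # 2. thinning spurs
    cand <- which(!isLoop & e$len < spurLength &
                  ((deg[e$from] == 1L & deg[e$to] >= 3L) |
                   (deg[e$to] == 1L & deg[e$from] >= 3L)))
    if (length(cand)) {
      i <- cand[1]
      tip <- if (deg[e$from[i]] == 1L) e$from[i] else e$to[i]
      alive[tip] <- FALSE
      e <- e[-i, , drop = FALSE]
      next
    }
    # 3. split junctions: two branch nodes joined by an edge, closer (in the
    # image plane) than any two genuine junctions can be
    eucl <- sqrt((nodes$row[e$from] - nodes$row[e$to])^2 +
                 (nodes$col[e$from] - nodes$col[e$to])^2)
    cand <- which(!isLoop & pmin(e$len, eucl) < mergeLength &
                  deg[e$from] >= 3L & deg[e$to] >= 3L)
    if (length(cand)) {
      i <- cand[1]
      a <- min(e$from[i], e$to[i]); b <- max(e$from[i], e$to[i])
      nodes$row[a] <- (nodes$row[a] + nodes$row[b]) / 2
      nodes$col[a] <- (nodes$col[a] + nodes$col[b]) / 2
      e <- e[-i, , drop = FALSE]
      e$from[e$from == b] <- a; e$to[e$to == b] <- a
      swap <- e$from > e$to
      tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
      alive[b] <- FALSE
      next
    }
    # 4. splice degree-2 nodes left behind by pruning/merging
    hasLoop <- unique(e$from[isLoop])
    cand <- which(alive & deg == 2L & !(seq_len(v) %in% hasLoop))
    spliced <- FALSE
    for (nd in cand) {
      inc <- which((e$from == nd | e$to == nd) & !isLoop)
      if (length(inc) != 2L) next
      a <- if (e$from[inc[1]] == nd) e$to[inc[1]] else e$from[inc[1]]
      b <- if (e$from[inc[2]] == nd) e$to[inc[2]] else e$from[inc[2]]
      newLen <- sum(e$len[inc])
      e <- e[-inc, , drop = FALSE]
      e <- rbind(e, data.frame(from = min(a, b), to = max(a, b), len = newLen))
      alive[nd] <- FALSE
      spliced <- TRUE
      break
    }
    if (!spliced) break
  }
  keep <- which(alive)
  remap <- integer(v); remap[keep] <- seq_along(keep)
  isLoop <- e$from == e$to
  deg <- tabulate(c(e$from[!isLoop], e$to[!isLoop]), nbins = v) +
         2L * tabulate(e$from[isLoop], nbins = v)
  nodes <- nodes[keep, , drop = FALSE]
  nodes$id <- seq_along(keep)
  nodes$kind <- ifelse(deg[keep] <= 1L, "endpoint", "branch")
  rownames(nodes) <- NULL
  loops <- data.frame(node = remap[e$from[isLoop]], length_px = e$len[isLoop])
  e <- e[!isLoop, , drop = FALSE]
  if (nrow(e)) {
    f <- remap[e$from]; t2 <- remap[e$to]
    key <- paste(pmin(f, t2), pmax(f, t2))
    lenAgg <- tapply(e$len, key, min)
    lenTot <- tapply(e$len, key, sum)
    cnt <- table(key)
    ord <- names(lenAgg)
    parts <- do.call(rbind, strsplit(ord, " "))
    edges <- data.frame(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]),
                        length_px = as.numeric(lenAgg),
                        multiplicity = as.integer(cnt[ord]),
                        length_total_px = as.numeric(lenTot[ord]))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        length_px = numeric(), multiplicity = integer(),
                        length_total_px = numeric())
  }
  VeinGraph(nodes, edges, loops, graph@orphanCycleCount)
}

#' Extract an undirected vein graph from a binary mask
#'
#' The full conversion chain: skeletonize, optionally magnify 2x, detect
#' endpoint/branch pixels, merge adjacent node pixels, trace edges, clean
#' skeleton-scale artifacts, and keep the largest connected component.
#'
#' @param mask logical matrix, vein = TRUE.
#' @param magnify apply 2x magnification before node extraction (used for
#'   dense networks where branch points sit close together).
#' @param criterion branch-point criterion, see \code{\link{detectNodePixels}}.
#' @param keepLargest keep only the largest connected component (default);
#'   set FALSE to retain all components.
#' @param clean apply \code{\link{cleanGraph}} (default TRUE).
#' @param ... cleanup thresholds passed to \code{\link{cleanGraph}}.
#' @return a \code{\linkS4class{VeinGraph}}.
#' @export
extractGraph <- function(mask, magnify = FALSE, criterion = c("count", "runs"),
                         keepLargest = TRUE, clean = TRUE, ...) {
  criterion <- match.arg(criterion)
  mask <- asMask(mask)
  if (!any(mask)) {
    warning("empty mask: returning empty graph")
    return(VeinGraph())
  }
  sk <- skeletonize(mask)
  if (magnify) sk <- magnify2x(sk)
  np <- detectNodePixels(sk, criterion)
  ni <- mergeAdjacentNodes(np, dim(sk))
  g <- traceEdges(sk, ni)
  if (clean) g <- cleanGraph(g, ...)
  if (keepLargest) g <- largestComponent(g) else g
}
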