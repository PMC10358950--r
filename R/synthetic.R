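#' Generate a random planar venation graph
#'
#' Samples anchor points uniformly inside the image (inset by twice the
#' stroke width so rasterized strokes never touch the border), triangulates
#' them (Delaunay), keeps a minimum spanning tree of the triangulation, and
#' then retains each remaining triangulation edge independently with
#' probability \code{loopiness}. The result is a connected planar simple
#' graph whose cycle rank grows with \code{loopiness}: 0 gives a spanning
#' tree, 1 the full triangulation.
#'
#' Two geometric validity rules make the graph resolvable at the requested
#' stroke width, so that rasterization is homotopy-equivalent to the graph
#' and junctions stay compact: (1) pairwise anchor spacing must exceed eight
#' stroke widths (areoles are much wider than the veins bounding them);
#' (2) no anchor may lie within three stroke widths of a non-incident
#' triangulation edge, nor subtend an angle-equivalent corridor (a quarter of
#' its distance to the nearer edge endpoint) — violating anchors are re-drawn
#' from the seeded stream until the triangulation is valid. Sampling that
#' cannot satisfy the rules errors out.
#'
#' Two RNG streams are used so the edge-retention draw is reproducible
#' independently of how many rejection draws anchor sampling needed:
#' anchors use \code{seed}, retention uses \code{seed + 1}.
#'
#' @param spec a \code{\linkS4class{VenationSpec}}.
#' @return a \code{\linkS4class{VeinGraph}}; anchor nodes keep their sampled
#'   (real-valued) coordinates, node kind reflects degree (1 = endpoint,
#'   2 = passthrough, >= 3 = branch), edge lengths are Euclidean.
#' @export
generatePlanarGraph <- function(spec) {
  validObject(spec)
  h <- spec@imageSize[1]; w <- spec@imageSize[2]
  margin <- 2 * spec@strokeWidth
  # enforced anchor spacing: well above the junction-blob scale, so genuine
  # graph structure stays separable from rasterization/thinning artifacts
  minDist <- 8 * spec@strokeWidth
  corridor <- 3 * spec@strokeWidth
  pts <- withSeed(spec@seed, {
    drawPoint <- function(p) {
      for (try in seq_len(3000L)) {
        cand <- c(runif(1, margin + 1, h - margin), runif(1, margin + 1, w - margin))
        if (nrow(p) == 0L ||
            min(sqrt(rowSums(sweep(p, 2, cand)^2))) > minDist) return(cand)
      }
      stop("imageSize too small to place ", spec@nAnchors,
           " anchors with spacing > 8*strokeWidth")
    }
    p <- matrix(NA_real_, 0, 2)
    for (i in seq_len(spec@nAnchors)) p <- rbind(p, drawPoint(p))
    # iterative validity repair: re-draw anchors that sit too close to a
    # non-incident Delaunay edge (corridor rule: pinch/face-closure control)
    # or subtend too shallow an angle between incident edges at some vertex
    # (fan rule: junction-compactness control)
    minAngle <- 15 * pi / 180
    for (it in seq_len(400L)) {
      dd <- deldir::deldir(x = p[, 2], y = p[, 1], suppressMsge = TRUE)$delsgs
      worst <- 0; who <- 0L
      for (k in seq_len(nrow(dd))) {
        a <- c(dd$y1[k], dd$x1[k]); b <- c(dd$y2[k], dd$x2[k])
        v <- b - a; L2 <- sum(v^2)
        for (j in seq_len(nrow(p))) {
          if (j == dd$ind1[k] || j == dd$ind2[k]) next
          tt <- max(0, min(1, sum((p[j, ] - a) * v) / L2))
          d <- sqrt(sum((p[j, ] - (a + tt * v))^2))
          viol <- corridor - d
          if (viol > worst) { worst <- viol; who <- j }
        }
      }
      nbr <- lapply(seq_len(nrow(p)), function(j)
        c(dd$ind2[dd$ind1 == j], dd$ind1[dd$ind2 == j]))
      for (vtx in seq_len(nrow(p))) {
        nb <- nbr[[vtx]]
        if (length(nb) < 2L) next
        ang <- atan2(p[nb, 1] - p[vtx, 1], p[nb, 2] - p[vtx, 2])
        o <- order(ang)
        gaps <- diff(c(ang[o], ang[o[1]] + 2 * pi))
        bad <- which(gaps < minAngle)
        for (g in bad) {
          # re-draw the nearer of the two fan neighbors
          pair <- nb[o][c(g, if (g == length(o)) 1L else g + 1L)]
          dists <- sqrt(rowSums((p[pair, , drop = FALSE] -
                                 rep(p[vtx, ], each = 2))^2))
          viol <- (minAngle - gaps[g]) * 60  # px-scale severity
          if (viol > worst) { worst <- viol; who <- pair[which.min(dists)] }
        }
      }
      if (who == 0L) break
      p[who, ] <- drawPoint(p[-who, , drop = FALSE])
    }
    if (who != 0L)
      stop("could not find a geometrically valid anchor configuration; ",
           "reduce nAnchors or strokeWidth, or enlarge imageSize")
    p
  })
  tri <- deldir::deldir(x = pts[, 2], y = pts[, 1], suppressMsge = TRUE)
  del <- tri$delsgs
  edges <- cbind(pmin(del$ind1, del$ind2), pmax(del$ind1, del$ind2))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  len <- sqrt((pts[edges[, 1], 1] - pts[edges[, 2], 1])^2 +
              (pts[edges[, 1], 2] - pts[edges[, 2], 2])^2)
  g <- igraph::make_empty_graph(spec@nAnchors, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::E(g)$weight <- len
  igraph::E(g)$idx <- seq_len(nrow(edges))
  mstIdx <- sort(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$idx)
  extra <- setdiff(seq_len(nrow(edges)), mstIdx)
  keepExtra <- withSeed(spec@seed + 1L, extra[runif(length(extra)) < spec@loopiness])
  keep <- sort(c(mstIdx, keepExtra))
  e <- data.frame(from = edges[keep, 1], to = edges[keep, 2],
                  length_px = len[keep], multiplicity = 1L)
  deg <- tabulate(c(e$from, e$to), nbins = spec@nAnchors)
  nodes <- data.frame(id = seq_len(spec@nAnchors), row = pts[, 1], col = pts[, 2],
                      kind = ifelse(deg == 1L, "endpoint",
                                    ifelse(deg == 2L, "passthrough", "branch")))
  VeinGraph(nodes, e)
}

#' Reduce a graph to its topological (homeomorphism) skeleton
#'
#' Suppresses degree-2 passthrough nodes by fusing their two incident edges,
#' folding the result into the simple-view-plus-bookkeeping representation:
#' parallel reduced paths become multiplicity, paths closing on a single node
#' become self-loops, and cycles whose every node has degree 2 become orphan
#' cycles. This is the graph a pixel-level extractor can see, since degree-2
#' points are indistinguishable from edge interiors; use it to compare
#' synthetic ground truth with \code{\link{extractGraph}} output.
#'
#' @param graph a \code{\linkS4class{VeinGraph}}.
#' @return a \code{\linkS4class{VeinGraph}} with only endpoint/branch nodes.
#' @export
reduceGraph <- function(graph) {
  # multigraph edge list; self-loops represented as from == to
  ed <- graph@edges
  mult <- if (nrow(ed)) rep(seq_len(nrow(ed)), ed$multiplicity) else integer()
  e <- data.frame(from = ed$from[mult], to = ed$to[mult], len = ed$length_px[mult])
  if (nrow(graph@loops)) e <- rbind(e, data.frame(from = graph@loops$node,
                                                  to = graph@loops$node,
                                                  len = graph@loops$length_px))
  orphans <- graph@orphanCycleCount
  v <- nNodes(graph)
  alive <- rep(TRUE, v)
  repeat {
    deg <- tabulate(c(e$from, e$to), nbins = v)  # self-loops count twice
    cand <- which(alive & deg == 2L)
    # only suppress nodes whose two edge-slots are two distinct non-loop edges
    picked <- NA_integer_
    for (nd in cand) {
      inc <- which(e$from == nd | e$to == nd)
      if (length(inc) == 2L && all(e$from[inc] != e$to[inc])) { picked <- nd; break }
      if (length(inc) == 1L && e$from[inc] == e$to[inc]) {
        # isolated self-loop on a degree-2 node: a node-free cycle
        e <- e[-inc, , drop = FALSE]
        alive[nd] <- FALSE
        orphans <- orphans + 1L
        picked <- 0L
        break
      }
    }
    if (is.na(picked)) break
    if (picked == 0L) next
    inc <- which(e$from == picked | e$to == picked)
    a <- ifelse(e$from[inc[1]] == picked, e$to[inc[1]], e$from[inc[1]])
    b <- ifelse(e$from[inc[2]] == picked, e$to[inc[2]], e$from[inc[2]])
    newLen <- sum(e$len[inc])
    e <- e[-inc, , drop = FALSE]
    e <- rbind(e, data.frame(from = a, to = b, len = newLen))
    alive[picked] <- FALSE
  }
  keep <- which(alive)
  remap <- integer(v); remap[keep] <- seq_along(keep)
  nodes <- graph@nodes[keep, , drop = FALSE]
  nodes$id <- seq_along(keep)
  deg <- tabulate(c(e$from, e$to), nbins = v)
  nodes$kind <- ifelse(deg[keep] <= 1L, "endpoint", "branch")
  rownames(nodes) <- NULL
  loops <- e[e$from == e$to, , drop = FALSE]
  e <- e[e$from != e$to, , drop = FALSE]
  if (nrow(e)) {
    f <- pmin(remap[e$from], remap[e$to]); t2 <- pmax(remap[e$from], remap[e$to])
    key <- paste(f, t2)
    agg <- tapply(e$len, key, min)
    tot <- tapply(e$len, key, sum)
    cnt <- table(key)
    ord <- names(agg)
    parts <- do.call(rbind, strsplit(ord, " "))
    edges <- data.frame(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]),
                        length_px = as.numeric(agg), multiplicity = as.integer(cnt[ord]),
                        length_total_px = as.numeric(tot[ord]))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        length_px = numeric(), multiplicity = integer(),
                        length_total_px = numeric())
  }
  loopDf <- data.frame(node = remap[loops$from], length_px = loops$len)
  VeinGraph(nodes, edges, loopDf, orphans)
}

#' Rasterize a vein graph to a binary image
#'
#' Draws every edge of the graph as a straight stroke between its node
#' centroids: the union of the Bresenham line (guaranteeing 8-connectivity)
#' and all pixels within \code{(strokeWidth - 1) / 2} of the segment. Strokes
#' falling outside the canvas are clipped with a warning.
#'
#' @param graph a \code{\linkS4class{VeinGraph}} with node coordinates.
#' @param strokeWidth stroke width in pixels (1 draws a bare Bresenham line).
#' @param imageSize integer (rows, cols).
#' @return logical matrix, vein = TRUE.
#' @export
rasterizeGraph <- function(graph, strokeWidth = 3L, imageSize = c(512L, 512L)) {
  h <- imageSize[1]; w <- imageSize[2]
  img <- matrix(FALSE, h, w)
  nodes <- graph@nodes
  if (nEdges(graph) == 0 && nrow(nodes) == 0) return(img)
  radius <- (strokeWidth - 1) / 2
  clipped <- FALSE
  drawSeg <- function(r0, c0, r1, c1) {
    bl <- bresenhamLine(r0, c0, r1, c1)
    oob <- bl[, 1] < 1 | bl[, 1] > h | bl[, 2] < 1 | bl[, 2] > w
    if (any(oob)) { clipped <<- TRUE; bl <- bl[!oob, , drop = FALSE] }
    img[bl] <<- TRUE
    if (radius > 0) {
      rlo <- max(1, floor(min(r0, r1) - radius)); rhi <- min(h, ceiling(max(r0, r1) + radius))
      clo <- max(1, floor(min(c0, c1) - radius)); chi <- min(w, ceiling(max(c0, c1) + radius))
      if (rlo > rhi || clo > chi) return(invisible())
      rr <- rlo:rhi; ccv <- clo:chi
      gr <- matrix(rr, length(rr), length(ccv))
      gc <- matrix(ccv, length(rr), length(ccv), byrow = TRUE)
      # distance from pixel centers to the segment
      vx <- r1 - r0; vy <- c1 - c0
      L2 <- vx^2 + vy^2
      tt <- if (L2 == 0) 0 else pmin(1, pmax(0, ((gr - r0) * vx + (gc - c0) * vy) / L2))
      dd <- sqrt((gr - (r0 + tt * vx))^2 + (gc - (c0 + tt * vy))^2)
      img[rlo:rhi, clo:chi] <<- img[rlo:rhi, clo:chi] | (dd <= radius)
    }
  }
  e <- graph@edges
  for (k in seq_len(nrow(e)))
    drawSeg(nodes$row[e$from[k]], nodes$col[e$from[k]],
            nodes$row[e$to[k]], nodes$col[e$to[k]])
  if (clipped) warning("stroke clipped at image bounds")
  # quantization cleanup: enclosed background pockets smaller than the stroke
  # footprint cannot represent graph faces (every face has inradius well above
  # the stroke radius); filling them keeps the image homotopy-equivalent to
  # the drawn graph
  fillSmallHoles(img, maxArea = strokeWidth^2)
}

# fill 4-connected background components not touching the border whose area
# is at most maxArea pixels
fillSmallHoles <- function(mask, maxArea) {
  if (maxArea < 1) return(mask)
  lab <- cpp_label4(!mask)
  k <- max(lab)
  if (k == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], k)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  fill <- setdiff(which(areas <= maxArea), border)
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}

#' Degrade a binary vein image into a noisy grayscale rendering
#'
#' Emulates backlit untreated-leaf imaging: veins dark on a lighter, textured
#' background. Degradations, applied in order: (1) gap insertion removes small
#' square patches of foreground (lost-connectivity failure mode), (2) intensity
#' synthesis (veins 0.2, background 0.8) plus smooth background texture of
#' amplitude \code{backgroundLevel}, (3) dark speckle noise at rate
#' \code{speckleRate}, (4) Gaussian blur with sd \code{blurSigma}. Deterministic
#' given \code{seed}; with all rates 0 and no blur the output is a two-level
#' image with exactly the input's support.
#'
#' @param binary logical matrix, vein = TRUE.
#' @param backgroundLevel amplitude of smooth background texture, in [0, 1].
#' @param blurSigma Gaussian blur sd in pixels (0 = none).
#' @param gapRate approximate fraction of foreground removed as gaps, [0, 1].
#' @param speckleRate fraction of pixels darkened as speckles, [0, 1].
#' @param seed RNG seed.
#' @param gapHalfWidth half-width of each square gap patch in pixels.
#' @return numeric matrix in [0, 1].
#' @export
degradeImage <- function(binary, backgroundLevel = 0.1, blurSigma = 0.8,
                         gapRate = 0.02, speckleRate = 0.005, seed = 1L,
                         gapHalfWidth = 3L) {
  stopifnot(all(c(backgroundLevel, gapRate, speckleRate) >= 0),
            all(c(gapRate, speckleRate) <= 1))
  withSeed(seed, {
    fg <- binary
    nfg <- sum(fg)
    if (gapRate > 0 && nfg > 0) {
      nGaps <- ceiling(gapRate * nfg / (2 * gapHalfWidth + 1)^1.5)
      centers <- which(fg)
      pick <- sample(centers, min(nGaps, length(centers)))
      nr <- nrow(fg)
      for (p in pick) {
        r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
        rs <- max(1, r - gapHalfWidth):min(nr, r + gapHalfWidth)
        cs <- max(1, cc - gapHalfWidth):min(ncol(fg), cc + gapHalfWidth)
        fg[rs, cs] <- FALSE
      }
    }
    img <- matrix(0.8, nrow(fg), ncol(fg))
    if (backgroundLevel > 0) {
      tex <- matrix(runif(length(fg), -1, 1), nrow(fg), ncol(fg))
      tex <- as.matrix(EBImage::gblur(tex, sigma = 6))
      tex <- tex / max(abs(tex))
      img <- img + backgroundLevel * tex
    }
    img[fg] <- 0.2
    if (speckleRate > 0) {
      n <- round(speckleRate * length(img))
      if (n > 0) img[sample(length(img), n)] <- 0.25
    }
    if (blurSigma > 0) img <- as.matrix(EBImage::gblur(img, sigma = blurSigma))
    clamp01(img)
  })
}

#' Hand-specified toy skeleton patterns
#'
#' One-pixel-wide drawn patterns with their expected vein graphs, for testing
#' node detection and edge tracing: \code{"line"} (2 endpoints, 1 edge),
#' \code{"Y"} (1 branch + 3 endpoints, 3 edges), \code{"H"} (2 branches +
#' 4 endpoints, 5 edges), \code{"cycle_with_tail"} (1 branch + 1 endpoint,
#' 1 tail edge + 1 self-loop) and \code{"bare_cycle"} (no nodes, 1 orphan
#' cycle).
#'
#' @param name one of \code{"line"}, \code{"Y"}, \code{"H"},
#'   \code{"cycle_with_tail"}, \code{"bare_cycle"}.
#' @return list with \code{image} (logical matrix) and \code{graph}
#'   (expected \code{\linkS4class{VeinGraph}}).
#' @export
toyPattern <- function(name = c("line", "Y", "H", "cycle_with_tail", "bare_cycle")) {
  name <- match.arg(name)
  img <- matrix(FALSE, 48L, 48L)
  draw <- function(r0, c0, r1, c1) img[bresenhamLine(r0, c0, r1, c1)] <<- TRUE
  nd <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(id = seq_len(nrow(m)), row = m[, 1], col = m[, 2],
               kind = ifelse(m[, 3] == 1, "endpoint", "branch"))
  }
  ring <- function() {
    draw(14, 14, 14, 32); draw(32, 14, 32, 32)
    draw(14, 14, 32, 14); draw(14, 32, 32, 32)
  }
  switch(name,
    line = {
      draw(10, 5, 10, 30)
      list(image = img,
           graph = VeinGraph(nd(10, 5, 1, 10, 30, 1),
                             data.frame(from = 1L, to = 2L, length_px = 25, multiplicity = 1L)))
    },
    Y = {
      draw(20, 20, 8, 8); draw(20, 20, 8, 32); draw(20, 20, 34, 20)
      list(image = img,
           graph = VeinGraph(nd(8, 8, 1, 8, 32, 1, 20, 20, 0, 34, 20, 1),
                             data.frame(from = c(1L, 2L, 3L), to = c(3L, 3L, 4L),
                                        length_px = c(12 * sqrt(2), 12 * sqrt(2), 14),
                                        multiplicity = 1L)))
    },
    H = {
      draw(8, 10, 32, 10); draw(8, 30, 32, 30); draw(20, 10, 20, 30)
      list(image = img,
           graph = VeinGraph(nd(8, 10, 1, 8, 30, 1, 20, 10, 0, 20, 30, 0,
                                32, 10, 1, 32, 30, 1),
                             data.frame(from = c(1L, 2L, 3L, 3L, 4L),
                                        to = c(3L, 4L, 4L, 5L, 6L),
                                        length_px = c(12, 12, 20, 12, 12),
                                        multiplicity = 1L)))
    },
    cycle_with_tail = {
      ring(); draw(14, 23, 2, 23)
      list(image = img,
           graph = VeinGraph(nd(2, 23, 1, 14, 23, 0),
                             data.frame(from = 1L, to = 2L, length_px = 12, multiplicity = 1L),
                             loops = data.frame(node = 2L, length_px = 72)))
    },
    bare_cycle = {
      ring()
      list(image = img, graph = VeinGraph(orphanCycles = 1L))
    })
}

#' Generate a ground-truthed synthetic venation sample
#'
#' Runs \code{\link{generatePlanarGraph}} and \code{\link{rasterizeGraph}} for
#' a spec, optionally followed by \code{\link{degradeImage}}.
#'
#' @param spec a \code{\linkS4class{VenationSpec}}.
#' @param degrade NULL for a clean binary sample, or a named list of arguments
#'   for \code{\link{degradeImage}} (the sample's seed is reused unless given).
#' @return a \code{\linkS4class{GroundTruthSample}}.
#' @export
makeGroundTruthSample <- function(spec, degrade = NULL) {
  g <- generatePlanarGraph(spec)
  img <- rasterizeGraph(g, spec@strokeWidth, spec@imageSize)
  gray <- matrix(numeric(), 0, 0)
  if (!is.null(degrade)) {
    if (is.null(degrade$seed)) degrade$seed <- spec@seed
    gray <- do.call(degradeImage, c(list(binary = img), degrade))
  }
  new("GroundTruthSample", graph = g, binaryImage = img, grayImage = gray, spec = spec)
}
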