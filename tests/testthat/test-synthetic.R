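test_that("planar graph generation spans the loopiness range", {
  spT <- VenationSpec(25, 0, 3, c(512, 512), seed = 11)
  gT <- generatePlanarGraph(spT)
  expect_equal(nEdges(gT), nNodes(gT) - 1L)  # spanning tree
  expect_equal(cycleRank(gT), 0L)

  spF <- VenationSpec(25, 1, 3, c(512, 512), seed = 11)
  gF <- generatePlanarGraph(spF)
  # full triangulation: compare edge count against an independent deldir call
  # on the same anchor coordinates
  pts <- nodeTable(gF)
  dd <- deldir::deldir(x = pts$col, y = pts$row, suppressMsge = TRUE)$delsgs
  nDel <- nrow(unique(cbind(pmin(dd$ind1, dd$ind2), pmax(dd$ind1, dd$ind2))))
  expect_equal(nEdges(gF), nDel)
  expect_equal(cycleRank(gF), nDel - nNodes(gF) + 1L)

  expect_error(VenationSpec(2, 0.5, 3, c(512, 512), 1), "nAnchors")
})

test_that("seeded edge retention is reproducible by an independent replay", {
  sp <- VenationSpec(50, 0.5, 3, c(512, 512), seed = 1)
  g <- generatePlanarGraph(sp)
  # independent oracle: full triangulation of the same anchors, hand-rolled
  # Kruskal MST, then the same seeded retention stream
  full <- generatePlanarGraph(VenationSpec(50, 1, 3, c(512, 512), seed = 1))
  ed <- edgeTable(full)
  ord <- order(ed$length_px)
  parent <- seq_len(nNodes(full))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  inMst <- logical(nrow(ed))
  for (k in ord) {
    a <- find(ed$from[k]); b <- find(ed$to[k])
    if (a != b) { parent[a] <- b; inMst[k] <- TRUE }
  }
  extra <- which(!inMst)
  set.seed(sp@seed + 1L)
  kept <- sum(runif(length(extra)) < sp@loopiness)
  expect_equal(cycleRank(g), kept)
  expect_equal(nEdges(g), sum(inMst) + kept)
})

test_that("mean retained extra edges matches p * (E_delaunay - (V - 1))", {
  nSeeds <- 200
  p <- 0.4
  extras <- numeric(nSeeds)
  expected <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    full <- generatePlanarGraph(VenationSpec(12, 1, 2, c(192, 192), seed = s))
    g <- generatePlanarGraph(VenationSpec(12, p, 2, c(192, 192), seed = s))
    extras[s] <- nEdges(g) - (nNodes(g) - 1L)
    expected[s] <- p * (nEdges(full) - (nNodes(full) - 1L))
  }
  se <- sd(extras - expected) / sqrt(nSeeds)
  expect_lt(abs(mean(extras) - mean(expected)), 3 * se)
})

test_that("rasterization draws Bresenham-exact 1-px strokes and clips", {
  g <- VeinGraph(data.frame(id = 1:2, row = c(10, 40), col = c(12, 47),
                            kind = "endpoint"),
                 data.frame(from = 1L, to = 2L, length_px = NA, multiplicity = 1L))
  img <- rasterizeGraph(g, strokeWidth = 1L, imageSize = c(64L, 64L))
  expect_equal(sum(img), nrow(bresenhamLine(10, 12, 40, 47)))

  empty <- rasterizeGraph(VeinGraph(), 3L, c(32L, 32L))
  expect_false(any(empty))

  gOut <- VeinGraph(data.frame(id = 1:2, row = c(10, 10), col = c(5, 80),
                               kind = "endpoint"),
                    data.frame(from = 1L, to = 2L, length_px = NA, multiplicity = 1L))
  expect_warning(rasterizeGraph(gOut, 1L, c(32L, 32L)), "clipped")
})

test_that("a rasterized triangle has exactly one hole", {
  tri <- VeinGraph(data.frame(id = 1:3, row = c(10, 50, 50), col = c(30, 10, 55),
                              kind = "branch"),
                   data.frame(from = c(1L, 1L, 2L), to = c(2L, 3L, 3L),
                              length_px = NA, multiplicity = 1L))
  img <- rasterizeGraph(tri, strokeWidth = 3L, imageSize = c(64L, 64L))
  top <- imageTopology(img)
  expect_equal(top$components, 1L)
  expect_equal(top$cycleRank, 1L)   # Euler number 0
  expect_equal(top$euler, 0)
})

test_that("image degradation is seeded, monotone in gaps, and exact when off", {
  s <- sampleFixture(3, imageSize = c(256L, 256L), nAnchors = 12L)
  clean <- degradeImage(s@binaryImage, backgroundLevel = 0, blurSigma = 0,
                        gapRate = 0, speckleRate = 0, seed = 5)
  expect_equal(sort(unique(as.vector(clean))), c(0.2, 0.8))
  expect_identical(clean < 0.5, s@binaryImage)

  gapped <- degradeImage(s@binaryImage, backgroundLevel = 0, blurSigma = 0,
                         gapRate = 0.1, speckleRate = 0, seed = 5)
  expect_lt(sum(gapped < 0.5), sum(s@binaryImage))

  d1 <- degradeImage(s@binaryImage, seed = 7)
  d2 <- degradeImage(s@binaryImage, seed = 7)
  expect_identical(d1, d2)
  d3 <- degradeImage(s@binaryImage, seed = 8)
  expect_false(identical(d1, d3))
})

test_that("toy patterns carry their expected graphs", {
  expected <- list(
    line = c(V = 2, E = 1, loops = 0, orphans = 0),
    Y = c(V = 4, E = 3, loops = 0, orphans = 0),
    H = c(V = 6, E = 5, loops = 0, orphans = 0),
    cycle_with_tail = c(V = 2, E = 1, loops = 1, orphans = 0),
    bare_cycle = c(V = 0, E = 0, loops = 0, orphans = 1))
  for (nm in names(expected)) {
    t <- toyPattern(nm)
    e <- expected[[nm]]
    expect_equal(nNodes(t$graph), e[["V"]], info = nm)
    expect_equal(nEdges(t$graph), e[["E"]], info = nm)
    expect_equal(selfLoopCount(t$graph), e[["loops"]], info = nm)
    expect_equal(orphanCycleCount(t$graph), e[["orphans"]], info = nm)
  }
  y <- toyPattern("Y")
  expect_equal(sum(nodeTable(y$graph)$kind == "branch"), 1L)
  expect_equal(unname(nodeDegrees(y$graph)[nodeTable(y$graph)$kind == "branch"]), 3L)
  expect_error(toyPattern("spiral"))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- makeGroundTruthSample(VenationSpec(20, 0.5, 3, c(384, 384), seed = 9))
  b <- makeGroundTruthSample(VenationSpec(20, 0.5, 3, c(384, 384), seed = 9))
  expect_identical(a@binaryImage, b@binaryImage)
  expect_identical(nodeTable(a@graph), nodeTable(b@graph))
  expect_identical(edgeTable(a@graph), edgeTable(b@graph))
})

test_that("graph reduction folds passthrough chains, loops and bare cycles", {
  # path a-b-c with b passthrough reduces to one edge of summed length
  nodes <- data.frame(id = 1:3, row = c(0, 0, 0), col = c(0, 10, 25),
                      kind = c("endpoint", "passthrough", "endpoint"))
  e <- data.frame(from = c(1L, 2L), to = c(2L, 3L), length_px = c(10, 15),
                  multiplicity = 1L)
  r <- reduceGraph(VeinGraph(nodes, e))
  expect_equal(nNodes(r), 2L)
  expect_equal(edgeTable(r)$length_px, 25)

  # two parallel passthrough paths between two degree-3 junctions fold into
  # a multiplicity-2 edge
  nodes2 <- data.frame(id = 1:6, row = c(0, 0, 5, -5, 0, 0),
                       col = c(0, 20, 10, 10, -10, 30),
                       kind = c("branch", "branch", "passthrough",
                                "passthrough", "endpoint", "endpoint"))
  e2 <- data.frame(from = c(1L, 3L, 1L, 4L, 1L, 2L),
                   to = c(3L, 2L, 4L, 2L, 5L, 6L),
                   length_px = c(11, 11, 11, 11, 10, 10), multiplicity = 1L)
  r2 <- reduceGraph(VeinGraph(nodes2, e2))
  expect_equal(nNodes(r2), 4L)
  expect_equal(sum(edgeTable(r2)$multiplicity), 4L)  # 2 tails + the double edge
  expect_equal(max(edgeTable(r2)$multiplicity), 2L)
  expect_equal(cycleRank(r2), 1L)

  # triangle hanging off one junction reduces to a self-loop there
  nodes2b <- data.frame(id = 1:4, row = c(0, 0, 10, 5), col = c(0, 10, 5, -5),
                        kind = c("branch", "passthrough", "passthrough", "endpoint"))
  e2b <- data.frame(from = c(1L, 1L, 2L, 1L), to = c(2L, 3L, 3L, 4L),
                    length_px = c(10, 8, 8, 7), multiplicity = 1L)
  r2b <- reduceGraph(VeinGraph(nodes2b, e2b))
  expect_equal(nNodes(r2b), 2L)
  expect_equal(selfLoopCount(r2b), 1L)
  expect_equal(cycleRank(r2b), 1L)

  # 3-cycle of passthrough nodes collapses to one orphan cycle
  nodes3 <- data.frame(id = 1:3, row = c(0, 10, 0), col = c(0, 5, 10),
                       kind = "passthrough")
  e3 <- data.frame(from = c(1L, 1L, 2L), to = c(2L, 3L, 3L),
                   length_px = 10, multiplicity = 1L)
  r3 <- reduceGraph(VeinGraph(nodes3, e3))
  expect_equal(nNodes(r3), 0L)
  expect_equal(orphanCycleCount(r3), 1L)
  expect_equal(cycleRank(r3), 1L)
})
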