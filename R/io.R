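#' Read an image from PNG or TIFF
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix (grayscale, [0, 1]) or H x W x 3 array (RGB).
#' @export
readImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask logical matrix, vein = TRUE.
#' @param path output path.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a grayscale image as PNG
#'
#' @param gray numeric matrix in [0, 1].
#' @param path output path.
#' @export
writeGrayPNG <- function(gray, path) {
  png::writePNG(clamp01(gray), path)
  invisible(path)
}

#' Read a 0/255 PNG mask
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
readMaskPNG <- function(path) {
  m <- readImage(path)
  if (length(dim(m)) == 3) m <- toGrayscale(m)
  m > 0.5
}

#' Write a vein graph as GraphML
#'
#' Node attributes \code{kind}, \code{row}, \code{col}; edge attributes
#' \code{length_px}, \code{multiplicity} (simple view; self-loop and
#' orphan-cycle counts go into graph attributes).
#'
#' @param graph a \code{\linkS4class{VeinGraph}}.
#' @param path output path (.graphml).
#' @export
writeGraphML <- function(graph, path) {
  g <- asIgraph(graph)
  g <- igraph::set_graph_attr(g, "self_loop_count", selfLoopCount(graph))
  g <- igraph::set_graph_attr(g, "orphan_cycle_count", orphanCycleCount(graph))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML vein graph written by \code{\link{writeGraphML}}
#'
#' @param path GraphML path.
#' @return a \code{\linkS4class{VeinGraph}} (self-loop path lengths are not
#'   round-tripped, only their count).
#' @export
readGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  nodes <- data.frame(id = seq_len(n),
                      row = igraph::vertex_attr(g, "row"),
                      col = igraph::vertex_attr(g, "col"),
                      kind = igraph::vertex_attr(g, "kind"))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      length_px = igraph::edge_attr(g, "length_px"),
                      multiplicity = as.integer(igraph::edge_attr(g, "multiplicity")))
  nl <- igraph::graph_attr(g, "self_loop_count")
  loops <- data.frame(node = integer(), length_px = numeric())
  if (!is.null(nl) && nl > 0)
    loops <- data.frame(node = rep(NA_integer_, nl), length_px = NA_real_)
  oc <- igraph::graph_attr(g, "orphan_cycle_count")
  VeinGraph(nodes, edges, loops, if (is.null(oc)) 0L else as.integer(oc))
}

#' Write a plain edge-list TSV
#'
#' Columns: from, to, length_px, multiplicity.
#'
#' @param graph a \code{\linkS4class{VeinGraph}}.
#' @param path output path.
#' @export
writeEdgeTSV <- function(graph, path) {
  utils::write.table(edgeTable(graph), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
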