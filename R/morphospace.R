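#' Cross-validated random-forest species classification
#'
#' Stratified k-fold cross-validation of a random forest on feature vectors:
#' fold assignment shuffles within each class under the given seed,
#' out-of-fold predictions are pooled into one confusion matrix, and
#' accuracy, per-class recall/precision and the per-cell Jaccard index
#' C_ij / (row_i + col_j - C_ij) are derived from it. Deterministic for a
#' fixed seed.
#'
#' @param features n x p numeric matrix or data.frame (rows = samples).
#' @param labels factor or character vector of class labels, length n.
#' @param k number of folds (default 5); every class must have >= k samples.
#' @param seed RNG seed controlling fold assignment and forest fitting.
#' @param ntree trees per forest (default 500).
#' @param mtry variables per split (default floor(sqrt(p))).
#' @return list of class \code{"ClassificationReport"}: \code{confusion}
#'   (rows = true), \code{accuracy}, \code{recall}, \code{precision},
#'   \code{jaccard}, \code{folds}, \code{seed}.
#' @export
classifyCV <- function(features, labels, k = 5L, seed = 1L, ntree = 500L,
                       mtry = NULL) {
  X <- as.matrix(features)
  y <- factor(labels)
  n <- nrow(X)
  stopifnot(length(y) == n)
  sizes <- table(y)
  if (any(sizes < k))
    stop("every class needs at least k samples for stratified ", k, "-fold CV")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  folds <- integer(n)
  withSeed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    pred <- factor(rep(levels(y)[1], n), levels = levels(y))
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- randomForest::randomForest(X[!test, , drop = FALSE], y[!test],
                                        ntree = ntree, mtry = mtry)
      pred[test] <- predict(fit, X[test, , drop = FALSE])
    }
    cm <- table(true = y, predicted = pred)
    structure(list(confusion = unclass(cm),
                   accuracy = sum(diag(cm)) / n,
                   recall = diag(cm) / rowSums(cm),
                   precision = diag(cm) / colSums(cm),
                   jaccard = confusionJaccard(unclass(cm)),
                   folds = folds, seed = seed),
              class = "ClassificationReport")
  })
}

# per-cell Jaccard index of a confusion matrix
confusionJaccard <- function(cm) {
  out <- cm * 0
  rs <- rowSums(cm); cs <- colSums(cm)
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
    denom <- rs[i] + cs[j] - cm[i, j]
    out[i, j] <- if (denom > 0) cm[i, j] / denom else 0
  }
  out
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("Stratified CV random forest: accuracy %.3f (%d classes, %d samples)\n",
              x$accuracy, nrow(x$confusion), sum(x$confusion)))
  print(x$confusion)
  cat("recall:   ", paste(sprintf("%.3f", x$recall), collapse = " "), "\n")
  cat("precision:", paste(sprintf("%.3f", x$precision), collapse = " "), "\n")
  invisible(x)
}

#' PCA morphospace of venation feature vectors
#'
#' Column-centered (and, by default, unit-scaled) singular value
#' decomposition. Zero-variance columns are centered but not scaled and get
#' zero loadings. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so the morphospace orientation is
#' reproducible.
#'
#' @param features n x p matrix (n >= 2).
#' @param standardize scale columns to unit variance (default TRUE).
#' @param m number of components to keep (default all = min(n - 1, p)).
#' @return list of class \code{"MorphospaceResult"}: \code{scores} (n x m),
#'   \code{loadings} (p x m, orthonormal columns), \code{explainedVariance}
#'   (ratios, non-increasing), \code{center}, \code{scale},
#'   \code{standardized}.
#' @export
fitPCA <- function(features, standardize = TRUE, m = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sds <- sqrt(colMeans(Xc^2) * n / (n - 1))
  scl <- rep(1, ncol(X))
  if (standardize) scl[sds > 0] <- sds[sds > 0]
  Xs <- sweep(Xc, 2, scl, "/")
  sv <- svd(Xs)
  ev <- sv$d^2 / sum(sv$d^2)
  mmax <- sum(sv$d > max(sv$d) * 1e-12)
  if (is.null(m)) m <- mmax else m <- min(m, length(sv$d))
  load <- sv$v[, seq_len(m), drop = FALSE]
  scores <- sv$u[, seq_len(m), drop = FALSE] %*% diag(sv$d[seq_len(m)], m, m)
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(m)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(load) <- colnames(X)
  structure(list(scores = scores, loadings = load,
                 explainedVariance = ev[seq_len(m)],
                 center = ctr, scale = scl, standardized = standardize),
            class = "MorphospaceResult")
}

#' @export
print.MorphospaceResult <- function(x, ...) {
  cat("PCA morphospace:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  cat("explained variance ratios:",
      paste(sprintf("%.3f", head(x$explainedVariance, 5)), collapse = " "),
      if (length(x$explainedVariance) > 5) "..." else "", "\n")
  invisible(x)
}

#' Egonet-neighbor histograms per group
#'
#' For each graph, the per-node egonet-neighbor counts are histogrammed into
#' the given bins and normalized to frequencies; per group, bin-wise mean and
#' standard deviation across graphs are returned. Tree-like venation
#' concentrates at two egonet neighbors (endpoint egos), highly looping
#' venation at six (degree-3 egos with disjoint second neighborhoods).
#'
#' @param graphs list of \code{\linkS4class{VeinGraph}} objects.
#' @param groups factor/character of group labels, one per graph (default:
#'   one group).
#' @param breaks histogram bin breaks (default integer bins 0..10, right-open,
#'   final bin absorbing larger counts).
#' @return data.frame with \code{group}, \code{bin} (left edge), \code{mean},
#'   \code{sd} (sd = 0 for single-graph groups).
#' @export
egonetHistogram <- function(graphs, groups = NULL, breaks = 0:10) {
  if (length(graphs) == 0) stop("empty graph list")
  if (is.null(groups)) groups <- rep("all", length(graphs))
  groups <- as.character(groups)
  stopifnot(length(groups) == length(graphs))
  nb <- length(breaks)
  freq <- t(vapply(graphs, function(g) {
    v <- computeNodeFeatures(g)$egonet_neighbors
    v <- pmin(v, breaks[nb])  # absorb overflow into the last bin
    counts <- tabulate(match(v, breaks), nbins = nb)
    counts / length(v)
  }, numeric(nb)))
  out <- do.call(rbind, lapply(unique(groups), function(gr) {
    f <- freq[groups == gr, , drop = FALSE]
    sds <- apply(f, 2, function(col) if (nrow(f) > 1) stats::sd(col) else 0)
    data.frame(group = gr, bin = breaks, mean = colMeans(f), sd = sds)
  }))
  rownames(out) <- NULL
  out
}

#' Graph size summary with optional area densities
#'
#' @param graph a non-empty \code{\linkS4class{VeinGraph}}.
#' @param areaCm2 optional leaf area; when given, node and edge densities per
#'   cm^2 are included.
#' @return named list: \code{nNodes}, \code{nEdges}, and if area given
#'   \code{nodesPerCm2}, \code{edgesPerCm2}.
#' @export
summarizeGraph <- function(graph, areaCm2 = NULL) {
  if (nNodes(graph) == 0) stop("empty graph")
  out <- list(nNodes = nNodes(graph), nEdges = nEdges(graph))
  if (!is.null(areaCm2)) {
    if (areaCm2 <= 0) stop("area must be > 0")
    out$nodesPerCm2 <- out$nNodes / areaCm2
    out$edgesPerCm2 <- out$nEdges / areaCm2
  }
  out
}
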