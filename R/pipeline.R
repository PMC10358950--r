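#' Pipeline configuration
#'
#' Flat key-value configuration for \code{\link{runPipeline}}. Unknown keys
#' are rejected; the resolved configuration is written next to the outputs of
#' every run.
#'
#' @param ... overrides of the defaults listed below.
#' @return named list of class \code{"PipelineConfig"}.
#' @export
veinConfig <- function(...) {
  defaults <- list(
    segment = FALSE,        # input is grayscale: run the tile segmenter
    magnify = FALSE,        # 2x magnification before node extraction
    classify = FALSE,       # run classifyCV (needs labels)
    pca = FALSE,            # fit the PCA morphospace
    branchCriterion = "runs",
    tileSize = 512L,
    margin = 16L,
    probThreshold = 0.5,
    claheClip = 2,
    claheGrid = 8L,
    thresholdMode = "otsu",
    cvFolds = 5L,
    ntree = 500L,
    standardizePca = TRUE,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "PipelineConfig")
}

#' Run the image-to-features pipeline over a batch of leaves
#'
#' For every input image: read, segment if requested (grayscale inputs through
#' the overlap-tile harness with the reference segmenter) or binarize, extract
#' the vein graph, write per-leaf GraphML and edge TSV, and collect the
#' 28-dimensional feature vector. Per-leaf failures are logged and skipped.
#' Optionally runs cross-validated classification (labels required) and the
#' PCA morphospace on the batch feature matrix. Idempotent for fixed inputs,
#' config and seed.
#'
#' @param input directory containing PNG/TIFF images, or a character vector
#'   of image paths.
#' @param outputDir output directory (created if needed).
#' @param config a \code{\link{veinConfig}}.
#' @param labels optional per-leaf class labels (named by file base name or
#'   in input order) enabling classification.
#' @return invisibly, a list with \code{features} (data.frame), \code{report}
#'   (classification or NULL), \code{pca} (or NULL), \code{log} (character).
#' @export
runPipeline <- function(input, outputDir, config = veinConfig(), labels = NULL) {
  files <- if (length(input) == 1 && dir.exists(input))
    sort(list.files(input, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                    ignore.case = TRUE))
  else as.character(input)
  if (length(files) == 0) stop("no input images found")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  graphDir <- file.path(outputDir, "graphs")
  dir.create(graphDir, showWarnings = FALSE)
  logLines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    logLines <<- c(logLines, line)
  }
  rows <- list()
  for (f in files) {
    id <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      img <- readImage(f)
      if (length(dim(img)) == 3) img <- toGrayscale(img)
      mask <- if (all(img %in% c(0, 1))) img > 0.5  # 0/255 PNG masks pass through
      else if (config$segment)
        segmentImage(img, referenceSegmenter(), config$tileSize, config$margin,
                     config$probThreshold)
      else makeTrainingMask(img, config$claheClip, config$claheGrid,
                            config$thresholdMode)
      g <- extractGraph(mask, magnify = config$magnify,
                        criterion = config$branchCriterion)
      if (nNodes(g) == 0) stop("no vein network found")
      writeGraphML(g, file.path(graphDir, paste0(id, ".graphml")))
      writeEdgeTSV(g, file.path(graphDir, paste0(id, ".tsv")))
      fv <- featureVector(g)
      note("%s: %d nodes, %d edges, %d self-loops, %d orphan cycles",
           id, nNodes(g), nEdges(g), selfLoopCount(g), orphanCycleCount(g))
      c(list(leaf = id), as.list(fv))
    }, error = function(e) {
      note("%s: SKIPPED (%s)", id, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[id]] <- res
  }
  if (length(rows) == 0) stop("all inputs failed")
  features <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(features) <- NULL
  write.csv(features, file.path(outputDir, "features.csv"), row.names = FALSE)
  report <- NULL
  if (isTRUE(config$classify)) {
    if (is.null(labels)) stop("classification requested but no labels given")
    lab <- if (!is.null(names(labels))) labels[features$leaf] else labels
    report <- classifyCV(features[, -1], lab, k = config$cvFolds,
                         seed = config$seed, ntree = config$ntree)
    jsonlite::write_json(
      list(accuracy = report$accuracy, recall = as.list(report$recall),
           precision = as.list(report$precision),
           confusion = unclass(report$confusion)),
      file.path(outputDir, "classification.json"), auto_unbox = TRUE, digits = NA)
  }
  pca <- NULL
  if (isTRUE(config$pca) && nrow(features) >= 2) {
    pca <- fitPCA(as.matrix(features[, -1]), standardize = config$standardizePca)
    write.csv(data.frame(leaf = features$leaf, pca$scores),
              file.path(outputDir, "pca_scores.csv"), row.names = FALSE)
    write.csv(data.frame(feature = rownames(pca$loadings), pca$loadings),
              file.path(outputDir, "pca_loadings.csv"), row.names = FALSE)
  }
  jsonlite::write_json(unclass(config), file.path(outputDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(logLines, file.path(outputDir, "pipeline.log"))
  invisible(list(features = features, report = report, pca = pca, log = logLines))
}

#' Write a grid of ground-truthed synthetic samples to disk
#'
#' For every combination of loopiness value and seed, generates a
#' \code{\linkS4class{GroundTruthSample}} and writes the binary image (PNG),
#' the ground-truth planar graph (GraphML), and a JSON manifest recording the
#' spec. Running the same call twice produces identical files.
#'
#' @param dir output directory.
#' @param loopiness numeric vector of loopiness values.
#' @param seeds integer vector of seeds.
#' @param nAnchors,strokeWidth,imageSize forwarded to
#'   \code{\link{VenationSpec}}.
#' @param degrade optional argument list for \code{\link{degradeImage}}; adds
#'   a grayscale PNG per sample.
#' @return data.frame manifest (one row per sample) with file paths.
#' @export
writeGroundTruthSamples <- function(dir, loopiness = c(0.05, 0.95), seeds = 1:3,
                                    nAnchors = 30L, strokeWidth = 3L,
                                    imageSize = c(512L, 512L), degrade = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(loopiness = loopiness, seed = seeds, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- VenationSpec(nAnchors, grid$loopiness[i], strokeWidth, imageSize,
                       grid$seed[i])
    s <- makeGroundTruthSample(sp, degrade)
    id <- sprintf("sample_l%03d_s%03d", round(grid$loopiness[i] * 100), grid$seed[i])
    maskPath <- file.path(dir, paste0(id, "_mask.png"))
    writeMaskPNG(s@binaryImage, maskPath)
    grayPath <- NA_character_
    if (length(s@grayImage)) {
      grayPath <- file.path(dir, paste0(id, "_gray.png"))
      writeGrayPNG(s@grayImage, grayPath)
    }
    gPath <- file.path(dir, paste0(id, ".graphml"))
    writeGraphML(s@graph, gPath)
    manifest <- list(id = id, nAnchors = nAnchors, loopiness = grid$loopiness[i],
                     strokeWidth = strokeWidth, imageSize = imageSize,
                     seed = grid$seed[i],
                     nNodes = nNodes(s@graph), nEdges = nEdges(s@graph))
    jsonlite::write_json(manifest, file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(id = id, mask = maskPath, gray = grayPath, graph = gPath,
               loopiness = grid$loopiness[i], seed = grid$seed[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
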