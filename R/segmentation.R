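#' Convert an RGB image to grayscale
#'
#' Standard luminance weighting (0.299 R + 0.587 G + 0.114 B), quantized to
#' 8-bit levels. Single-channel input passes through unchanged.
#'
#' @param img numeric matrix (returned as-is) or H x W x 3 array with values
#'   in [0, 1] (values above 1 are assumed 8-bit and divided by 255).
#' @return numeric matrix in [0, 1], quantized to 255ths.
#' @export
toGrayscale <- function(img) {
  if (is.matrix(img)) return(img)
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] %in% c(3L, 4L)))
    stop("expected a matrix or an H x W x 3 RGB array")
  if (max(img) > 1) img <- img / 255
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  round(g * 255) / 255
}

# CLAHE wrapper tolerant of image sizes not divisible by the tile grid
# (EBImage requires exact multiples): reflect-pad, equalize, crop.
claheEnhance <- function(gray, clip = 2, grid = 8L) {
  nr <- nrow(gray); nc <- ncol(gray)
  pr <- (grid - nr %% grid) %% grid
  pc <- (grid - nc %% grid) %% grid
  padded <- padReflect(gray, 0L, pr, 0L, pc)
  eq <- as.matrix(EBImage::clahe(padded, nx = grid, ny = grid, limit = clip))
  eq[seq_len(nr), seq_len(nc), drop = FALSE]
}

# exhaustive-scan-free Otsu via EBImage; input in [0, 1]
otsuThreshold <- function(gray) {
  EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
}

#' Produce a training mask by contrast enhancement and thresholding
#'
#' The classical mask recipe used to build segmentation training targets from
#' high-quality cleared-leaf images without manual annotation: contrast-limited
#' adaptive histogram equalization (CLAHE), then a global threshold. Veins are
#' dark under transmitted light, so foreground = pixels below the threshold.
#'
#' @param gray numeric matrix in [0, 1].
#' @param claheClip CLAHE clip limit (default 2).
#' @param claheGrid CLAHE tile grid (default 8, i.e. 8 x 8 tiles).
#' @param threshold \code{"otsu"} (default) or a fixed numeric threshold
#'   (values > 1 are interpreted on the 0-255 scale).
#' @param applyClahe set FALSE to threshold the raw image.
#' @return logical matrix, vein = TRUE.
#' @export
makeTrainingMask <- function(gray, claheClip = 2, claheGrid = 8L,
                             threshold = "otsu", applyClahe = TRUE) {
  if (length(gray) == 0) stop("empty image")
  if (max(gray) == min(gray)) {
    warning("flat image: returning empty mask")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  x <- if (applyClahe) claheEnhance(gray, claheClip, claheGrid) else gray
  t0 <- if (identical(threshold, "otsu")) otsuThreshold(x)
        else { t <- as.numeric(threshold); if (t > 1) t / 255 else t }
  x < t0
}

#' Overlap-tile grid
#'
#' Tile origins for the overlap-tile inference protocol: the image is
#' reflection-padded by \code{margin} on every side (and further on the
#' bottom/right if needed to fit one tile), tiles of \code{tileSize} are
#' placed at stride \code{tileSize - 2 margin}, with the final origin clamped
#' to the padded canvas. At merge time each un-padded pixel is owned by
#' exactly one tile (the margin-cropped interior; at the image border the
#' interior extends to the tile edge through the padding).
#'
#' @param imageSize integer (rows, cols) of the un-padded image.
#' @param tileSize tile side in pixels (default 512).
#' @param margin border exclusion width in pixels (default 16).
#' @return object of class \code{"TileGrid"}: list with \code{tileSize},
#'   \code{margin}, \code{stride}, \code{imageSize}, \code{paddedSize},
#'   \code{nTiles} (rows, cols of the tile grid) and \code{origins}
#'   (data.frame of 1-based origins on the padded canvas).
#' @export
tileGrid <- function(imageSize, tileSize = 512L, margin = 16L) {
  stride <- tileSize - 2L * margin
  if (stride <= 0L) stop("margin too large: stride must be positive")
  padded <- pmax(tileSize, imageSize + 2L * margin)
  nTiles <- pmax(1L, ceiling((padded - tileSize) / stride) + 1L)
  orig1 <- pmin((seq_len(nTiles[1]) - 1L) * stride, padded[1] - tileSize) + 1L
  orig2 <- pmin((seq_len(nTiles[2]) - 1L) * stride, padded[2] - tileSize) + 1L
  origins <- expand.grid(row = orig1, col = orig2, KEEP.OUT.ATTRS = FALSE)
  origins <- origins[order(origins$row, origins$col), , drop = FALSE]
  rownames(origins) <- NULL
  structure(list(tileSize = as.integer(tileSize), margin = as.integer(margin),
                 stride = as.integer(stride), imageSize = as.integer(imageSize),
                 paddedSize = as.integer(padded), nTiles = as.integer(nTiles),
                 origins = origins),
            class = "TileGrid")
}

#' @export
print.TileGrid <- function(x, ...) {
  cat(sprintf("TileGrid: %dx%d tiles of %d px (margin %d, stride %d) over %dx%d image\n",
              x$nTiles[1], x$nTiles[2], x$tileSize, x$margin, x$stride,
              x$imageSize[1], x$imageSize[2]))
  invisible(x)
}

#' Cut an image into overlap tiles
#'
#' @param image numeric or logical matrix.
#' @param grid a \code{\link{tileGrid}} for \code{dim(image)}.
#' @return list of tiles, each a list with \code{origin} (1-based, padded
#'   canvas) and \code{tile} (tileSize x tileSize matrix).
#' @export
tileImage <- function(image, grid) {
  stopifnot(all(dim(image) == grid$imageSize))
  m <- grid$margin
  extra <- grid$paddedSize - dim(image) - 2L * m
  padded <- padReflect(image, m, m + extra[1], m, m + extra[2])
  lapply(seq_len(nrow(grid$origins)), function(i) {
    r <- grid$origins$row[i]; c <- grid$origins$col[i]
    list(origin = c(r, c),
         tile = padded[r:(r + grid$tileSize - 1L), c:(c + grid$tileSize - 1L)])
  })
}

# ownership: un-padded pixel index -> tile row/col index (1-based)
tileOwner <- function(grid) {
  own <- function(n, nt) pmin((seq_len(n) - 1L) %/% grid$stride, nt - 1L) + 1L
  list(row = own(grid$imageSize[1], grid$nTiles[1]),
       col = own(grid$imageSize[2], grid$nTiles[2]))
}

#' Merge overlap tiles back into an image
#'
#' Each output pixel is taken from the unique tile owning it (interior
#' ownership at stride spacing; the outer \code{margin} pixels of interior
#' tile boundaries are excluded, border tiles keep their margin at the image
#' border through the padding).
#'
#' @param tiles list as produced by \code{\link{tileImage}} (tiles may have
#'   been transformed, shape must be preserved).
#' @param grid the \code{\link{tileGrid}} used to cut them.
#' @return matrix of size \code{grid$imageSize}.
#' @export
mergeTiles <- function(tiles, grid) {
  if (length(tiles) != nrow(grid$origins)) stop("tile set does not cover the grid")
  for (t in tiles) if (!all(dim(t$tile) == grid$tileSize))
    stop("tile shape does not match the grid")
  out <- matrix(tiles[[1]]$tile[1], grid$imageSize[1], grid$imageSize[2])
  owner <- tileOwner(grid)
  key <- paste(grid$origins$row, grid$origins$col)
  for (ti in seq_len(grid$nTiles[1])) {
    for (tj in seq_len(grid$nTiles[2])) {
      rowsOut <- which(owner$row == ti)
      colsOut <- which(owner$col == tj)
      orig <- c(pmin((ti - 1L) * grid$stride, grid$paddedSize[1] - grid$tileSize) + 1L,
                pmin((tj - 1L) * grid$stride, grid$paddedSize[2] - grid$tileSize) + 1L)
      idx <- match(paste(orig[1], orig[2]), key)
      if (is.na(idx)) stop("coverage gap: missing tile at origin ", orig[1], ",", orig[2])
      tl <- tiles[[idx]]$tile
      # padded coords of owned pixels: un-padded + margin
      rIn <- rowsOut + grid$margin - orig[1] + 1L
      cIn <- colsOut + grid$margin - orig[2] + 1L
      out[rowsOut, colsOut] <- tl[rIn, cIn]
    }
  }
  out
}

#' Dice coefficient loss
#'
#' 1 - 2 |P intersect G| / (|P| + |G|); 0 for two empty masks.
#'
#' @param pred,truth logical matrices.
#' @return numeric in [0, 1].
#' @export
diceLoss <- function(pred, truth) {
  p <- sum(pred); g <- sum(truth)
  if (p + g == 0) return(0)
  1 - 2 * sum(pred & truth) / (p + g)
}

#' Reference classical segmenter
#'
#' A deterministic stand-in for a trained tile segmenter, satisfying the
#' segmenter contract (shape-preserving, probabilities in [0, 1]): per tile,
#' intensities are min-max normalized, an Otsu threshold is computed, and the
#' signed distance below the threshold is mapped linearly to [0, 1] so that
#' probability >= 0.5 exactly on the dark (vein) set. Optional per-tile
#' adaptive equalization can be enabled; it is off by default so that
#' darkening a pixel can never lower that pixel's vein probability.
#'
#' @param equalize apply CLAHE before thresholding (default FALSE).
#' @param claheClip,claheGrid CLAHE parameters when \code{equalize = TRUE}.
#' @return a function mapping a grayscale tile matrix to a probability matrix
#'   of identical shape.
#' @export
referenceSegmenter <- function(equalize = FALSE, claheClip = 2, claheGrid = 8L) {
  function(tile) {
    x <- tile
    if (max(x) == min(x)) return(matrix(0, nrow(x), ncol(x)))
    if (equalize) x <- claheEnhance(x, claheClip, claheGrid)
    rng <- range(x)
    x <- (x - rng[1]) / (rng[2] - rng[1])
    t0 <- otsuThreshold(x)
    s <- max(t0, 1 - t0)
    clamp01(0.5 + 0.5 * (t0 - x) / s)
  }
}

#' Segment a grayscale image with a pluggable tile segmenter
#'
#' Cuts the image into overlap tiles, applies the segmenter to each tile,
#' merges predictions with the margin-exclusion rule, and thresholds the
#' merged probability map.
#'
#' @param gray numeric matrix in [0, 1].
#' @param segmenter a function tile -> probability tile of identical shape
#'   (see \code{\link{referenceSegmenter}}).
#' @param tileSize,margin overlap-tile parameters (defaults 512 and 16).
#' @param probThreshold vein probability cutoff (default 0.5; foreground is
#'   probability >= cutoff).
#' @return logical matrix, vein = TRUE.
#' @export
segmentImage <- function(gray, segmenter = referenceSegmenter(),
                         tileSize = 512L, margin = 16L, probThreshold = 0.5) {
  grid <- tileGrid(dim(gray), tileSize, margin)
  tiles <- tileImage(gray, grid)
  preds <- lapply(tiles, function(t) {
    p <- segmenter(t$tile)
    if (!identical(dim(p), dim(t$tile)))
      stop("segmenter contract violation: output shape differs from input")
    if (min(p) < 0 || max(p) > 1)
      stop("segmenter contract violation: probabilities outside [0, 1]")
    list(origin = t$origin, tile = p)
  })
  mergeTiles(preds, grid) >= probThreshold
}

#' Segmentation training configuration contract
#'
#' The training recipe for a learned tile segmenter, recorded as a validated
#' configuration object: Dice coefficient loss, Adam optimizer at learning
#' rate 0.001, rotation/gamma/noise augmentation, and a residual-network-18
#' encoder pretrained on natural images. Training itself is out of scope for
#' this package (no deep-learning backend is required at analysis time); the
#' object documents the contract a trained segmenter is expected to follow.
#'
#' @param loss loss name (fixed: \code{"dice"}).
#' @param optimizer optimizer name (default \code{"adam"}).
#' @param learningRate positive learning rate (default 0.001).
#' @param augmentations character vector of augmentation names.
#' @param encoder encoder description.
#' @return list of class \code{"TrainingConfig"}.
#' @export
trainingConfig <- function(loss = "dice", optimizer = "adam", learningRate = 0.001,
                           augmentations = c("rotation", "gamma", "noise"),
                           encoder = "resnet18-imagenet") {
  if (learningRate <= 0) stop("learningRate must be > 0")
  structure(list(loss = loss, optimizer = optimizer, learningRate = learningRate,
                 augmentations = augmentations, encoder = encoder),
            class = "TrainingConfig")
}
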