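test_that("grayscale conversion uses 8-bit luminance weighting", {
  white <- array(1, c(4, 4, 3))
  expect_true(all(toGrayscale(white) == 1))

  rgb <- array(0, c(4, 4, 3))
  rgb[, , 1] <- 100 / 255; rgb[, , 2] <- 200 / 255; rgb[, , 3] <- 50 / 255
  g <- toGrayscale(rgb)
  expect_true(all(round(g * 255) == 153))

  m <- matrix(0.5, 3, 3)
  expect_identical(toGrayscale(m), m)
  expect_error(toGrayscale(array(0, c(3, 3, 2))), "RGB")
})

test_that("training masks binarize dark veins after contrast enhancement", {
  img <- matrix(200 / 255, 96, 96)
  img[40:56, 10:90] <- 50 / 255
  dark <- img < 100 / 255

  fixed <- makeTrainingMask(img, threshold = 128)
  expect_identical(fixed, dark)

  auto <- makeTrainingMask(img, threshold = "otsu")
  expect_identical(auto, dark)
  # the otsu threshold itself agrees with an exhaustive variance scan
  t1 <- venation:::otsuThreshold(img)
  t2 <- otsuScan(img)
  expect_true((img < t1)[42, 42] == (img <= t2)[42, 42])
  expect_identical(img < t1, img <= t2)

  expect_warning(flat <- makeTrainingMask(matrix(0.4, 32, 32)), "flat")
  expect_false(any(flat))
  expect_error(makeTrainingMask(matrix(numeric(), 0, 0)), "empty")
})

test_that("tile grids follow the stride arithmetic", {
  g1 <- tileGrid(c(512L, 512L), 512L, 16L)
  expect_equal(g1$stride, 480L)
  expect_equal(g1$nTiles, c(2L, 2L))
  expect_equal(nrow(g1$origins), 4L)       # 544x544 padded canvas, 4 tiles
  expect_equal(g1$paddedSize, c(544L, 544L))
  expect_equal(sort(unique(g1$origins$row)), c(1L, 33L))  # clamped to 544-512+1

  g2 <- tileGrid(c(480L, 480L), 512L, 16L)
  expect_equal(nrow(g2$origins), 1L)       # exactly one tile after padding

  tiles <- tileImage(matrix(runif(480 * 480), 480, 480), g2)
  expect_true(all(vapply(tiles, function(t) all(dim(t$tile) == c(512, 512)), logical(1))))

  expect_error(tileGrid(c(100L, 100L), 64L, 32L), "stride")
})

test_that("every unpadded pixel is owned by exactly one tile interior", {
  for (sz in list(c(512L, 512L), c(700L, 530L), c(100L, 200L))) {
    g <- tileGrid(sz, 256L, 16L)
    own <- venation:::tileOwner(g)
    expect_length(own$row, sz[1])
    expect_length(own$col, sz[2])
    expect_true(all(own$row >= 1 & own$row <= g$nTiles[1]))
    # ownership is a partition: each pixel appears once by construction;
    # verify owner interiors actually contain their pixels on the canvas
    for (ti in seq_len(g$nTiles[1])) {
      rows <- which(own$row == ti)
      orig <- min((ti - 1L) * g$stride, g$paddedSize[1] - g$tileSize) + 1L
      inTile <- rows + g$margin - orig + 1L
      expect_true(all(inTile >= 1 & inTile <= g$tileSize))
    }
  }
})

test_that("tile then merge is a bit-exact identity for random image sizes", {
  set.seed(31)
  for (rep in 1:6) {
    sz <- c(sample(64:600, 1), sample(64:600, 1))
    img <- matrix(runif(prod(sz)), sz[1], sz[2])
    g <- tileGrid(sz, 128L, 8L)
    merged <- mergeTiles(tileImage(img, g), g)
    expect_identical(merged, img, info = paste(sz, collapse = "x"))
  }
})

test_that("merged output reflects interior-region ownership exactly", {
  sz <- c(300L, 300L)
  g <- tileGrid(sz, 128L, 8L)
  tiles <- tileImage(matrix(0, sz[1], sz[2]), g)
  for (i in seq_along(tiles)) tiles[[i]]$tile[] <- i
  merged <- mergeTiles(tiles, g)
  own <- venation:::tileOwner(g)
  oracle <- outer(own$row, own$col,
                  function(r, c) (r - 1L) * g$nTiles[2] + c)
  # origins are sorted row-major, so tile index follows the same order
  expect_true(all(merged == oracle))
  expect_error(mergeTiles(tiles[-1], g), "cover")
})

test_that("dice loss has its unit anchors", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(diceLoss(a, a), 0)
  expect_equal(diceLoss(a, !a), 1)
  expect_equal(diceLoss(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
  b <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(diceLoss(a, b), 1 - 2 * 1 / (2 + 1))
})

test_that("the reference segmenter honours its contract", {
  seg <- referenceSegmenter()
  tile <- matrix(200 / 255, 64, 64)
  tile[20:40, 10:50] <- 50 / 255
  p <- seg(tile)
  expect_equal(dim(p), dim(tile))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all((p >= 0.5) == (tile < 100 / 255)))  # dark set scores >= 0.5
  expect_identical(seg(tile), p)                      # deterministic
  expect_true(all(seg(matrix(0.7, 16, 16)) == 0))     # flat tile: no veins
})

test_that("darkening a pixel never lowers its vein probability", {
  seg <- referenceSegmenter()
  set.seed(77)
  for (rep in 1:40) {
    tile <- matrix(runif(32 * 32, 0.2, 0.9), 32, 32)
    p0 <- seg(tile)
    i <- sample(length(tile), 1)
    tile2 <- tile
    tile2[i] <- max(0, tile[i] - runif(1, 0.05, 0.3))
    p1 <- seg(tile2)
    expect_gte(p1[i], p0[i] - 1e-12)
  }
})

test_that("segmentation pipeline thresholds merged probabilities", {
  s <- sampleFixture(8, loopiness = 0.4, nAnchors = 15L, imageSize = c(256L, 256L))
  gray <- degradeImage(s@binaryImage, backgroundLevel = 0, blurSigma = 0,
                       gapRate = 0, speckleRate = 0, seed = 1)
  mask <- segmentImage(gray, referenceSegmenter(), tileSize = 128L, margin = 8L)
  jac <- sum(mask & s@binaryImage) / sum(mask | s@binaryImage)
  expect_gte(jac, 0.95)

  allFg <- segmentImage(gray, function(t) matrix(1, nrow(t), ncol(t)),
                        tileSize = 128L, margin = 8L)
  expect_true(all(allFg))
  allBg <- segmentImage(gray, function(t) matrix(0, nrow(t), ncol(t)),
                        tileSize = 128L, margin = 8L)
  expect_false(any(allBg))
  expect_error(segmentImage(gray, function(t) t[1:10, 1:10, drop = FALSE],
                            tileSize = 128L, margin = 8L), "contract")
})

test_that("the training configuration contract validates", {
  cfg <- trainingConfig()
  expect_equal(cfg$loss, "dice")
  expect_equal(cfg$optimizer, "adam")
  expect_equal(cfg$learningRate, 0.001)
  expect_true(all(c("rotation", "gamma", "noise") %in% cfg$augmentations))
  expect_error(trainingConfig(learningRate = 0), "learningRate")
})
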