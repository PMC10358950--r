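#' Estimate a homography from point correspondences
#'
#' Normalized direct linear transform (DLT): both point sets are translated
#' and scaled to mean 0 and RMS distance sqrt(2), the 2n x 9 DLT system is
#' solved by SVD, and the de-normalized matrix is returned scaled so its
#' bottom-right entry is 1. Points are given as (x, y) = (col, row) pixel
#' coordinates.
#'
#' @param src,dst n x 2 matrices of corresponding points (n >= 4), columns
#'   (x, y).
#' @return 3x3 homography mapping source to destination coordinates.
#' @export
estimateHomography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n) stop("need at least 4 point correspondences")
  normalize <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = T, p = t(T %*% rbind(t(p), 1))[, 1:2, drop = FALSE])
  }
  ns <- normalize(src); nd <- normalize(dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y, -v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-9 * sv$d[1])
    stop("degenerate point configuration: homography not identifiable")
  h <- sv$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  if (abs(H[3, 3]) < 1e-12) stop("degenerate homography (h33 ~ 0)")
  H <- H / H[3, 3]
  if (abs(det(H)) < 1e-9 * max(abs(H))^3)
    stop("degenerate point configuration: estimated homography is singular")
  H
}

#' Warp an image through a homography
#'
#' Inverse-warp resampling: each output pixel is mapped back through the
#' inverse homography and sampled from the source (nearest neighbor for
#' logical masks, bilinear for grayscale). Out-of-bounds samples are
#' background (FALSE / 0).
#'
#' @param image logical or numeric matrix.
#' @param homography 3x3 matrix mapping source (x, y) to rectified (x, y),
#'   with x = col, y = row, or a \code{\linkS4class{CalibrationModel}}.
#' @param outputSize integer (rows, cols); defaults to the input size.
#' @param interpolation \code{"auto"} (nearest for logical, bilinear
#'   otherwise), \code{"nearest"} or \code{"bilinear"}.
#' @return matrix of size \code{outputSize}, same mode as the input.
#' @export
rectifyImage <- function(image, homography, outputSize = dim(image),
                         interpolation = c("auto", "nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  if (is(homography, "CalibrationModel")) homography <- homographyMatrix(homography)
  if (abs(det(homography)) < 1e-12) stop("singular homography")
  isBin <- is.logical(image)
  if (interpolation == "auto") interpolation <- if (isBin) "nearest" else "bilinear"
  Hi <- solve(homography)
  nrO <- outputSize[1]; ncO <- outputSize[2]
  xs <- rep(seq_len(ncO), each = nrO)   # x = col
  ys <- rep(seq_len(nrO), times = ncO)  # y = row
  p <- Hi %*% rbind(xs, ys, 1)
  sx <- p[1, ] / p[3, ]
  sy <- p[2, ] / p[3, ]
  src <- if (isBin) image + 0 else image
  nrI <- nrow(image); ncI <- ncol(image)
  val <- numeric(length(sx))
  if (interpolation == "nearest") {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= nrI & ci >= 1 & ci <= ncI
    val[ok] <- src[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sy); c0 <- floor(sx)
    fr <- sy - r0; fc <- sx - c0
    ok <- r0 >= 1 & (r0 + 1) <= nrI & c0 >= 1 & (c0 + 1) <= ncI
    # exact-grid points (fr = fc = 0) handled by the same weights
    i <- which(ok)
    if (length(i)) {
      v00 <- src[cbind(r0[i], c0[i])]
      v01 <- src[cbind(r0[i], c0[i] + 1)]
      v10 <- src[cbind(r0[i] + 1, c0[i])]
      v11 <- src[cbind(r0[i] + 1, c0[i] + 1)]
      val[i] <- v00 * (1 - fr[i]) * (1 - fc[i]) + v01 * (1 - fr[i]) * fc[i] +
                v10 * fr[i] * (1 - fc[i]) + v11 * fr[i] * fc[i]
    }
    # border row/column: fall back to nearest where bilinear support is cut
    edge <- which(!ok & sy >= 0.5 & sy <= nrI + 0.5 & sx >= 0.5 & sx <= ncI + 0.5)
    if (length(edge)) {
      ri <- pmin(pmax(round(sy[edge]), 1), nrI)
      ci <- pmin(pmax(round(sx[edge]), 1), ncI)
      val[edge] <- src[cbind(ri, ci)]
    }
  }
  out <- matrix(val, nrO, ncO)
  if (isBin) out > 0.5 else out
}

#' Estimate the area scale from a marker mask
#'
#' Pooled-pixel estimate over all square calibration markers: with
#' \code{nMarkers} markers of known physical area each, the scale is
#' \code{nMarkers * markerAreaCm2 / total marker pixels} (cm^2 per pixel).
#' The mask must contain exactly \code{nMarkers} 8-connected components.
#'
#' @param markerMask logical matrix with marker pixels TRUE.
#' @param nMarkers expected number of markers (e.g. 8 on the acquisition
#'   frame).
#' @param markerAreaCm2 physical area of one marker (default 1 cm^2).
#' @return cm^2 per pixel.
#' @export
estimateAreaScale <- function(markerMask, nMarkers, markerAreaCm2 = 1.0) {
  total <- sum(markerMask)
  if (total == 0) stop("marker mask is empty")
  k <- max(cpp_label8(markerMask))
  if (k != nMarkers)
    stop("marker detection error: found ", k, " components, expected ", nMarkers)
  nMarkers * markerAreaCm2 / total
}

#' Threshold blue calibration markers in an RGB image
#'
#' Thin HSV-range filter for the blue square markers; defaults cover typical
#' printed blue under daylight, all bounds exposed.
#'
#' @param rgb H x W x 3 array in [0, 1].
#' @param hueRange hue window in [0, 1] (default c(0.5, 0.78), cyan-to-blue).
#' @param minSaturation,minValue lower bounds in [0, 1].
#' @return logical matrix of marker pixels.
#' @export
blueMarkerMask <- function(rgb, hueRange = c(0.5, 0.78), minSaturation = 0.3,
                           minValue = 0.2) {
  stopifnot(length(dim(rgb)) == 3)
  hsv <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]), g = as.vector(rgb[, , 2]),
                            b = as.vector(rgb[, , 3]), maxColorValue = 1)
  m <- hsv[1, ] >= hueRange[1] & hsv[1, ] <= hueRange[2] &
       hsv[2, ] >= minSaturation & hsv[3, ] >= minValue
  matrix(m, dim(rgb)[1], dim(rgb)[2])
}

#' Leaf area from a mask and an area scale
#'
#' @param leafMask logical matrix, leaf pixels TRUE.
#' @param scale cm^2 per pixel (number or \code{\linkS4class{CalibrationModel}}).
#' @return area in cm^2.
#' @export
leafAreaCm2 <- function(leafMask, scale) {
  if (is(scale, "CalibrationModel")) scale <- areaScale(scale)
  if (is.na(scale) || scale <= 0) stop("area scale must be positive")
  sum(leafMask) * scale
}
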