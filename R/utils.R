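# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 8-neighborhood offsets in the deterministic walk order N, NE, E, SE, S, SW, W, NW
NB8 <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
             dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

#' Bresenham line pixels
#'
#' Integer pixel coordinates of the 8-connected Bresenham segment between two
#' pixels (inclusive of both ends).
#'
#' @param r0,c0,r1,c1 integer endpoints (row, col).
#' @return two-column integer matrix (row, col).
#' @export
bresenhamLine <- function(r0, c0, r1, c1) {
  r0 <- as.integer(round(r0)); c0 <- as.integer(round(c0))
  r1 <- as.integer(round(r1)); c1 <- as.integer(round(c1))
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  colnames(out) <- c("row", "col")
  out
}

#' Binary image topology
#'
#' Number of 8-connected foreground components, Euler characteristic (for
#' 8-connected foreground / 4-connected background, computed from 2x2 quad
#' pattern counts), and the cycle rank beta1 = components - Euler.
#'
#' @param mask logical matrix.
#' @return list with \code{components}, \code{euler}, \code{cycleRank}.
#' @export
imageTopology <- function(mask) {
  stopifnot(is.matrix(mask))
  dm <- dim(mask)
  mask <- as.logical(mask)
  dim(mask) <- dm
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  a <- m[-nr, -nc]; b <- m[-nr, -1]; cc <- m[-1, -nc]; d <- m[-1, -1]
  s <- a + b + cc + d
  q1 <- sum(s == 1L)
  q3 <- sum(s == 3L)
  qd <- sum(s == 2L & ((a & d) | (b & cc)))
  euler <- (q1 - q3 - 2L * qd) / 4
  comps <- max(cpp_label8(mask), 0L)
  list(components = as.integer(comps),
       euler = euler,
       cycleRank = as.integer(round(comps - euler)))
}

# Reflective ("symmetric", edge-inclusive) index extension for padding;
# supports padding wider than the image by recycling the reflection.
reflectIndex <- function(n, pre, post) {
  idx <- seq.int(1L - pre, n + post)
  period <- 2L * n
  j <- ((idx - 1L) %% period + period) %% period  # 0 .. 2n-1
  ifelse(j < n, j + 1L, period - j)
}

padReflect <- function(m, top, bottom, left, right) {
  ri <- reflectIndex(nrow(m), top, bottom)
  ci <- reflectIndex(ncol(m), left, right)
  m[ri, ci, drop = FALSE]
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Coerce any numeric/logical image to a logical vein mask.
asMask <- function(x) {
  if (is.logical(x)) return(x)
  x > 0.5
}
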