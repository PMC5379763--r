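## Geometric primitives for spherocylinder (rod) cells.
##
## A rod of total tip-to-tip length L and width W is the set of points within
## W/2 of its axis segment; the segment has length L - W (pole centers), so the
## two semicircular caps bring the total extent back to L.

## Endpoints (pole centers) of a cell's axis segment, in um.
cell_axis <- function(center, orientation, length, width) {
  half <- pmax(length - width, 0) / 2
  dx <- cos(orientation); dy <- sin(orientation)
  list(p1 = c(center[1] - half * dx, center[2] - half * dy),
       p2 = c(center[1] + half * dx, center[2] + half * dy))
}

## Distance from points (px, py) to segment p1-p2, plus the projection
## parameter t in [0,1]. Vectorized over points.
point_segment_distance <- function(px, py, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx * vx + vy * vy
  if (len2 < 1e-12) {
    d <- sqrt((px - p1[1])^2 + (py - p1[2])^2)
    return(list(dist = d, t = rep(0.5, length(px))))
  }
  t <- clamp(((px - p1[1]) * vx + (py - p1[2]) * vy) / len2, 0, 1)
  qx <- p1[1] + t * vx; qy <- p1[2] + t * vy
  list(dist = sqrt((px - qx)^2 + (py - qy)^2), t = t)
}

## Minimum distance between two segments, and the closest-approach direction
## (unit vector from segment a towards segment b).
segment_segment_distance <- function(a1, a2, b1, b2) {
  ## sample-based closest approach is exact enough for packing relaxation:
  ## refine the analytic candidates (endpoint-to-segment x4 + interior crossing)
  best <- Inf; pa <- a1; pb <- b1
  cand <- list(
    list(p = a1, s1 = b1, s2 = b2, from = "a"),
    list(p = a2, s1 = b1, s2 = b2, from = "a"),
    list(p = b1, s1 = a1, s2 = a2, from = "b"),
    list(p = b2, s1 = a1, s2 = a2, from = "b"))
  for (cc in cand) {
    pr <- point_segment_distance(cc$p[1], cc$p[2], cc$s1, cc$s2)
    q <- cc$s1 + pr$t * (cc$s2 - cc$s1)
    if (pr$dist < best) {
      best <- pr$dist
      if (cc$from == "a") { pa <- cc$p; pb <- q } else { pa <- q; pb <- cc$p }
    }
  }
  ## interior-interior case: solve the 2x2 linear system, clamp
  u <- a2 - a1; v <- b2 - b1; w0 <- a1 - b1
  A <- sum(u * u); B <- sum(u * v); C <- sum(v * v)
  D <- sum(u * w0); E <- sum(v * w0)
  den <- A * C - B * B
  if (den > 1e-12) {
    s <- clamp((B * E - C * D) / den, 0, 1)
    t <- clamp((A * E - B * D) / den, 0, 1)
    qa <- a1 + s * u; qb <- b1 + t * v
    d <- sqrt(sum((qa - qb)^2))
    if (d < best) { best <- d; pa <- qa; pb <- qb }
  }
  dirv <- pb - pa
  n <- sqrt(sum(dirv^2))
  if (n < 1e-9) dirv <- c(1, 0) else dirv <- dirv / n
  list(dist = best, dir = dirv)
}

## Exact area of the convex hull of a pixel set, treating pixels as unit
## squares (hull of the 4 corners of every pixel). Used by solidity().
pixel_hull_area <- function(rows, cols) {
  r <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  c2 <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  idx <- chull(c2, r)
  x <- c2[idx]; y <- r[idx]
  n <- length(idx)
  if (n < 3) return(length(rows))
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Solidity of a pixel region
#'
#' Ratio of the region area to the area of its convex hull; well-formed
#' single rods score close to 1, while branched unions of several cells
#' score lower. Pixels are treated as unit squares, so the hull of a filled
#' rectangle equals its pixel area exactly.
#'
#' @param pixels two-column matrix of (row, col) pixel coordinates.
#' @return solidity in (0, 1].
#' @export
solidity <- function(pixels) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2, nrow(pixels) >= 1)
  nrow(pixels) / pixel_hull_area(pixels[, 1], pixels[, 2])
}
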