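## Small shared helpers. Images are plain numeric matrices indexed [row, col],
## 1-based, top-left origin. Frame numbers are 1-based everywhere.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Shift a matrix by (dr, dc), padding with `fill`
#' @noRd
mat_shift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) == 0 || length(cs) == 0) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## Count of 8-neighbours that are TRUE, per pixel.
neighbor_count8 <- function(b) {
  m <- b * 1
  s <- matrix(0, nrow(b), ncol(b))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + mat_shift(m, dr, dc)
  }
  s
}

## Separable box mean filter with replicate padding (used by adaptive threshold).
box_mean <- function(m, win) {
  stopifnot(win %% 2 == 1)
  h <- (win - 1) / 2
  pad_run <- function(x, h) {
    n <- length(x)
    xp <- c(rep(x[1], h), x, rep(x[n], h))
    cs <- cumsum(xp)
    (cs[(2 * h + 1):(n + 2 * h)] - c(0, cs[seq_len(n - 1)])) / win
  }
  m1 <- apply(m, 2, pad_run, h = h)
  t(apply(m1, 1, pad_run, h = h))
}

## Separable Gaussian blur with replicate padding; sigma = 0 is identity.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-h:h, sd = sigma); k <- k / sum(k)
  conv_run <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], h), x, rep(x[n], h))
    as.numeric(stats::filter(xp, k, sides = 2))[(h + 1):(n + h)]
  }
  m1 <- apply(m, 2, conv_run)
  t(apply(m1, 1, conv_run))
}

## Bounding box of TRUE pixels: c(r1, r2, c1, c2); NULL when empty.
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  c(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2]))
}

## Pad a bbox by `pad` pixels, clipped to the image.
grow_bbox <- function(bb, pad, dim) {
  c(max(1, bb[1] - pad), min(dim[1], bb[2] + pad),
    max(1, bb[3] - pad), min(dim[2], bb[4] + pad))
}

crop_bbox <- function(m, bb) m[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]

## 8-connected labelling via EBImage; returns integer matrix.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
}

## Disc structuring element of given radius (odd-sized logical matrix).
disc_brush <- function(radius) {
  sz <- 2L * as.integer(radius) + 1L
  EBImage::makeBrush(sz, shape = "disc")
}

is_binary <- function(m) all(m %in% c(0, 1, TRUE, FALSE))

## Fill enclosed background holes smaller than max_area (noise speckle
## inside cells); larger enclosed structures (e.g. interface lines between
## several cells) are kept.
fill_small_holes <- function(mask, max_area) {
  inv <- !mask
  lab <- label_components(inv)
  if (max(lab) == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes < max_area), border)
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}

## Iteratively remove foreground pixels with at most two 8-neighbours:
## deletes 1-px tendrils and diagonal strings without eroding solid
## regions the way an opening would.
despur_binary <- function(mask, max_iter = 10) {
  for (i in seq_len(max_iter)) {
    del <- mask & neighbor_count8(mask) <= 2
    if (!any(del)) break
    mask <- mask & !del
  }
  mask
}

## Deterministic child seed derived from a base seed (kept below 2^31).
derive_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9176) %% 2147483587)
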