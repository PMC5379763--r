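## Collinear-object analysis: width (distance) curves along the ordered
## centerline, "deep valley" (bow-tie) detection, and splitting the object
## into single cells at valley positions.

#' Width curve of a collinear object
#'
#' For every ordered centerline point, the local width is the Euclidean
#' distance between the two boundary crossings of the line through the point
#' normal to the local centerline tangent (antipodal boundary pixels). The
#' curve is smoothed with a window-3 moving average.
#'
#' @param mask logical matrix, one collinear object.
#' @param centerline ordered (row, col) matrix; computed from the pruned
#'   skeleton when omitted.
#' @param prune_len spur-pruning length used when the centerline must be
#'   derived here.
#' @return list of class `distance_curve` with `centerline`, `widths` and
#'   `valley_indices` (empty until [find_deep_valleys()] is applied), or
#'   NULL for degenerate objects (centerline < 5 px: intact single cell).
#' @export
distance_curve <- function(mask, centerline = NULL, prune_len = 5) {
  if (is.null(centerline)) {
    cls <- classify_object(mask, prune_len = prune_len)
    if (cls$klass != "collinear") stop("distance_curve needs a collinear object")
    centerline <- order_centerline(cls$skeleton)
  }
  if (is.null(centerline) || nrow(centerline) < 5) return(NULL)
  n <- nrow(centerline)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    a <- centerline[max(1, i - 2), ]; b <- centerline[min(n, i + 2), ]
    tg <- c(b[1] - a[1], b[2] - a[2])
    nt <- sqrt(sum(tg^2)); if (nt < 1e-9) tg <- c(1, 0) else tg <- tg / nt
    nrm <- c(-tg[2], tg[1])
    widths[i] <- ray_width(mask, centerline[i, ], nrm)
  }
  sm <- widths
  if (n >= 3) sm[2:(n - 1)] <- (widths[1:(n - 2)] + widths[2:(n - 1)] + widths[3:n]) / 3
  structure(list(centerline = centerline, widths = sm,
                 valley_indices = integer(0)),
            class = "distance_curve")
}

## length of the in-mask chord through p along +-nrm (step 0.25 px)
ray_width <- function(mask, p, nrm, step = 0.25, max_r = 64) {
  reach <- function(sgn) {
    r <- 0
    repeat {
      r2 <- r + step
      q <- p + sgn * r2 * nrm
      qi <- round(q)
      if (qi[1] < 1 || qi[1] > nrow(mask) || qi[2] < 1 || qi[2] > ncol(mask) ||
          !mask[qi[1], qi[2]] || r2 > max_r) return(r)
      r <- r2
    }
  }
  reach(1) + reach(-1) + 1  # +1: the centre pixel's own extent
}

#' Detect deep valleys in a width curve
#'
#' A local minimum of the width curve qualifies as a deep valley iff the
#' ratio of its value to the nearest flanking local maximum is at most
#' `t_valley` on *both* sides. Plateaus count as single extrema (their
#' centre index is reported).
#'
#' @param widths numeric width curve (or a `distance_curve`).
#' @param t_valley threshold T, usually in \[0.65, 0.75\].
#' @return ordered integer indices of deep valleys (empty = intact cell).
#' @export
find_deep_valleys <- function(widths, t_valley = 0.70) {
  if (inherits(widths, "distance_curve")) widths <- widths$widths
  ex <- local_extrema(widths)
  if (length(ex$minima) == 0 || length(ex$maxima) == 0) return(integer(0))
  out <- integer(0)
  for (i in ex$minima) {
    lmax <- ex$maxima[ex$maxima < i]
    rmax <- ex$maxima[ex$maxima > i]
    if (length(lmax) == 0 || length(rmax) == 0) next
    lv <- widths[max(lmax)]; rv <- widths[min(rmax)]
    if (lv <= 0 || rv <= 0) next
    if (widths[i] / lv <= t_valley && widths[i] / rv <= t_valley)
      out <- c(out, i)
  }
  out
}

## Local extrema with plateau handling: runs of equal values collapse to
## their centre index. Minima are interior (both neighbouring runs
## higher); maxima also include the boundary runs when the adjacent
## interior run is lower - the flat plateau of a uniform-width cell at the
## curve end is the flanking maximum of a septum valley.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(minima = integer(0), maxima = integer(0)))
  r <- rle(x)
  k <- length(r$values)
  if (k < 2) return(list(minima = integer(0), maxima = integer(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  minima <- integer(0); maxima <- integer(0)
  for (j in seq_len(k)) {
    centre <- as.integer(floor((starts[j] + ends[j]) / 2))
    lower_l <- j > 1 && r$values[j - 1] < r$values[j]
    lower_r <- j < k && r$values[j + 1] < r$values[j]
    if ((j == 1 || lower_l) && (j == k || lower_r))
      maxima <- c(maxima, centre)
    if (j > 1 && j < k &&
        r$values[j - 1] > r$values[j] && r$values[j + 1] > r$values[j])
      minima <- c(minima, centre)
  }
  list(minima = minima, maxima = maxima)
}

#' Split a collinear object at deep-valley positions
#'
#' Object pixels are partitioned by assigning each pixel to its nearest
#' centerline point and cutting the centerline at the valley indices. A cut
#' producing a part smaller than `min_area_px` is ignored (weakest valley
#' first) and logged via a warning.
#'
#' @param mask logical matrix of the object.
#' @param curve a [distance_curve()] result.
#' @param valleys integer valley indices.
#' @param min_area_px minimum fragment area A in pixels.
#' @return list of parts, each with `pixels` (row/col matrix) and `centroid`
#'   (mean pixel coordinates).
#' @export
split_collinear <- function(mask, curve, valleys, min_area_px = 0) {
  px <- which(mask, arr.ind = TRUE)
  if (length(valleys) == 0)
    return(list(list(pixels = px, centroid = colMeans(px))))
  cl <- curve$centerline
  ## nearest centerline index per pixel
  d2 <- outer(px[, 1], cl[, 1], `-`)^2 + outer(px[, 2], cl[, 2], `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  valleys <- sort(valleys)
  repeat {
    grp <- findInterval(nearest, valleys + 0.5) + 1L
    sizes <- tabulate(grp, nbins = length(valleys) + 1L)
    if (min_area_px <= 0 || all(sizes >= min_area_px) || length(valleys) == 0)
      break
    ## drop the valley bounding the smallest undersized part (weaker side)
    small <- which.min(sizes)
    cand <- unique(c(if (small > 1) small - 1L else NULL,
                     if (small <= length(valleys)) small else NULL))
    drop_idx <- cand[which.max(curve$widths[valleys[cand]])]
    warning("collinear cut ignored: fragment below minimum area")
    valleys <- valleys[-drop_idx]
    if (length(valleys) == 0) {
      grp <- rep(1L, nrow(px)); break
    }
  }
  lapply(sort(unique(grp)), function(g) {
    p <- px[grp == g, , drop = FALSE]
    list(pixels = p, centroid = colMeans(p))
  })
}
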