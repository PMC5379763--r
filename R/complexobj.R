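## Complex-object analysis: watershed candidate extraction, solidity-guided
## "puzzle solving" of over-segmented fragments, the point-budget and
## minimum-fragment-area formulas, and small-fragment cleanup.

#' Watershed candidate cells inside a complex object
#'
#' Watershed transform of the negated Euclidean distance map with h-minima
#' suppression (h = 1 px). Over-segmentation is expected and is resolved by
#' [puzzle_solve()].
#'
#' @param mask logical matrix of the object.
#' @param markers optional integer matrix of marker labels (e.g. connected
#'   conservative-threshold cell cores). When present, markers are grown
#'   over the object by Voronoi propagation on the distance map, which
#'   restores the over-segmentation premise in dense regions where the
#'   plain distance-transform watershed under-segments fused slabs.
#' @return list with `labels` (integer fragment matrix) and `centers`
#'   (data.frame fragment, centroid_row, centroid_col, area_px).
#' @export
watershed_candidates <- function(mask, markers = NULL) {
  dt <- EBImage::distmap(EBImage::Image(mask * 1))
  if (!is.null(markers) && max(markers) >= 2) {
    ## split multi-cell marker blobs with the plain watershed on the marker
    ## mask itself (interface remnants narrow the cores), then grow
    mdt <- EBImage::distmap(EBImage::Image((markers > 0) * 1))
    mws <- EBImage::watershed(mdt, tolerance = 1, ext = 1)
    mlab <- matrix(as.integer(EBImage::imageData(mws)), nrow(mask), ncol(mask))
    mlab[markers == 0] <- 0L
    pg <- EBImage::propagate(dt, seeds = EBImage::Image(mlab),
                             mask = EBImage::Image(mask * 1) > 0.5)
    lab <- matrix(as.integer(EBImage::imageData(pg)), nrow(mask), ncol(mask))
  } else {
    ws <- EBImage::watershed(dt, tolerance = 1, ext = 1)
    lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(mask), ncol(mask))
  }
  lab[!mask] <- 0L
  ids <- sort(unique(lab[lab > 0]))
  lab <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
  centers <- fragment_centers(lab)
  list(labels = lab, centers = centers)
}

fragment_centers <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0)
    return(data.frame(fragment = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer()))
  out <- do.call(rbind, lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    data.frame(fragment = id, centroid_row = mean(w[, 1]),
               centroid_col = mean(w[, 2]), area_px = nrow(w))
  }))
  rownames(out) <- NULL
  out
}

#' Point budget for a complex object
#'
#' `N = ceil( 1/2 * C * CellLength * CellWidth / CalFactor^2 )` data points:
#' proportional to the number `C` of estimated candidate cell centres, with
#' the expected cell footprint in pixels as the per-cell budget.
#'
#' @param C candidate-centre count (>= 1).
#' @param species a [species_config()].
#' @return integer N.
#' @export
point_budget <- function(C, species) {
  if (C < 1) stop("point_budget requires at least one candidate centre")
  as.integer(ceiling(0.5 * C * species$cell_length * species$cell_width /
                     species$cal_factor^2))
}

#' Minimum fragment area A
#'
#' `A = 1/4 * pi * (CellWidth / CalFactor)^2` pixels: the area of the two
#' semicircular poles of a well-formed cell. Fragments below A are merged
#' into a touching neighbour.
#'
#' @param species a [species_config()].
#' @return A in pixels (numeric).
#' @export
min_fragment_area <- function(species) {
  0.25 * pi * (species$cell_width / species$cal_factor)^2
}

## -------------------------------------------------------------------------
## puzzle solving

## pairs of touching fragments (8-adjacency); returns 2-column matrix of ids
touching_pairs <- function(lab) {
  prs <- list()
  for (sh in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    a <- lab
    b <- mat_shift(lab, sh[1], sh[2], fill = 0L)
    sel <- a > 0 & b > 0 & a != b
    if (any(sel))
      prs[[length(prs) + 1L]] <- cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  }
  if (length(prs) == 0) return(matrix(integer(0), 0, 2))
  unique(do.call(rbind, prs))
}

## Width profile along the pruned skeleton of a merge candidate: 2 x
## distance map at skeleton pixels, in centerline order. Fast
## approximation used inside puzzle solving. Returns NULL when the cleaned
## region still has skeleton junctions (a branched union, not a chain).
region_width_profile <- function(mask, prune_len, wpx = NULL) {
  mask <- fill_small_holes(mask, max_area = ceiling(prune_len^2 / 2))
  cls <- classify_object(mask, prune_len = prune_len)
  if (cls$klass != "collinear") return(NULL)
  cl <- order_centerline(cls$skeleton)
  if (is.null(cl) || nrow(cl) < 5) return(list(centerline = cl, widths = NULL))
  dt <- matrix(as.numeric(EBImage::imageData(
    EBImage::distmap(EBImage::Image(mask * 1)))), nrow(mask), ncol(mask))
  w <- 2 * dt[cl]
  n <- length(w)
  sm <- w
  sm[2:(n - 1)] <- (w[1:(n - 2)] + w[2:(n - 1)] + w[3:n]) / 3
  list(centerline = cl, widths = sm)
}

#' Merge over-segmented watershed fragments ("puzzle solving")
#'
#' Iterative queue procedure. Two touching fragments may merge iff (a) the
#' merged region is still collinear (its pruned skeleton has no junctions),
#' (b) no deep valley exists along the merged centerline in the
#' neighbourhood of the shared boundary, and (c) the merged region's median
#' local width stays below 1.5 x the expected cell width (rejects
#' side-by-side parallel cells that the valley criterion cannot see). Among
#' feasible partners the merge maximizing post-merge solidity is chosen
#' (tie: smaller-area neighbour, then smaller fragment id); the merged
#' fragment is re-enqueued. Terminates because every merge reduces the
#' fragment count.
#'
#' @param lab integer fragment label matrix (from [watershed_candidates()]).
#' @param species a [species_config()].
#' @param t_valley deep-valley threshold.
#' @return list with `labels` (merged fragment matrix, compact ids) and
#'   `centers` (fragment centroid table).
#' @export
puzzle_solve <- function(lab, species, t_valley = 0.70) {
  wpx <- species$cell_width / species$cal_factor
  prune <- max(3, round(wpx))
  queue <- sort(unique(lab[lab > 0]))
  alive <- queue
  while (length(queue) > 0) {
    f <- queue[1]; queue <- queue[-1]
    if (!(f %in% alive)) next
    pairs <- touching_pairs(lab)
    nbrs <- unique(c(pairs[pairs[, 1] == f, 2], pairs[pairs[, 2] == f, 1]))
    if (length(nbrs) == 0) next
    best <- NULL
    for (g in sort(nbrs)) {
      mm <- lab == f | lab == g
      bb <- grow_bbox(mask_bbox(mm), 2, dim(lab))
      sub <- crop_bbox(mm, bb)
      prof <- region_width_profile(sub, prune, wpx)
      if (is.null(prof)) next                       # merged region branches
      if (!is.null(prof$widths)) {
        if (median(prof$widths) > 1.5 * wpx) next   # parallel-cell guard
        ## valleys near the shared boundary only
        shared <- shared_boundary_pixels(lab, f, g)
        if (nrow(shared) > 0) {
          shared[, 1] <- shared[, 1] - bb[1] + 1L
          shared[, 2] <- shared[, 2] - bb[3] + 1L
          vl <- find_deep_valleys(prof$widths, t_valley)
          if (length(vl) > 0) {
            cl <- prof$centerline
            d2 <- outer(cl[vl, 1], shared[, 1], `-`)^2 +
                  outer(cl[vl, 2], shared[, 2], `-`)^2
            if (any(sqrt(apply(d2, 1, min)) <= wpx)) next  # bow tie between them
          }
        }
      }
      px <- which(mm, arr.ind = TRUE)
      s <- solidity(px)
      ga <- sum(lab == g)
      if (is.null(best) || s > best$s + 1e-12 ||
          (abs(s - best$s) <= 1e-12 && ga < best$ga)) {
        best <- list(g = g, s = s, ga = ga)
      }
    }
    if (!is.null(best)) {
      lab[lab == best$g] <- f
      alive <- setdiff(alive, best$g)
      queue <- c(queue[queue != best$g], f)
    }
  }
  ids <- sort(unique(lab[lab > 0]))
  lab <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
  list(labels = lab, centers = fragment_centers(lab))
}

## pixels of fragment f adjacent to fragment g (and vice versa)
shared_boundary_pixels <- function(lab, f, g) {
  out <- list()
  for (sh in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    b <- mat_shift(lab, sh[1], sh[2], fill = 0L)
    sel <- (lab == f & b == g) | (lab == g & b == f)
    if (any(sel)) out[[length(out) + 1L]] <- which(sel, arr.ind = TRUE)
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 2))
  unique(do.call(rbind, out))
}

#' Refine puzzle-solved fragments with the deep-valley criterion
#'
#' Guarantees the over-segmentation premise the mixture stage relies on
#' (components can only be annihilated, never created): a fragment whose
#' width profile still contains deep valleys is split at them, and a
#' fragment wider than 1.5 cell widths across its principal axis - a fused
#' side-by-side pair that no distance-transform watershed can cut - is
#' split transversely. Superfluous splits are re-merged later by the MML
#' criterion or the minimum-area rule.
#'
#' @param lab integer fragment label matrix (after [puzzle_solve()]).
#' @param species a [species_config()].
#' @param t_valley deep-valley threshold.
#' @return refined label matrix (compact ids).
#' @export
refine_fragments <- function(lab, species, t_valley = 0.70) {
  wpx <- species$cell_width / species$cal_factor
  prune <- max(3, round(wpx))
  out <- matrix(0L, nrow(lab), ncol(lab))
  nxt <- 1L
  for (f in sort(unique(lab[lab > 0]))) {
    px <- which(lab == f, arr.ind = TRUE)
    assigned <- FALSE
    if (nrow(px) >= 8) {
      mm <- matrix(FALSE, nrow(lab), ncol(lab)); mm[px] <- TRUE
      bb <- grow_bbox(mask_bbox(mm), 2, dim(lab))
      sub <- crop_bbox(mm, bb)
      prof <- region_width_profile(sub, prune)
      if (!is.null(prof) && !is.null(prof$widths)) {
        v <- find_deep_valleys(prof$widths, t_valley)
        if (length(v) > 0) {
          spx <- which(sub, arr.ind = TRUE)
          d2 <- outer(spx[, 1], prof$centerline[, 1], `-`)^2 +
                outer(spx[, 2], prof$centerline[, 2], `-`)^2
          nearest <- max.col(-d2, ties.method = "first")
          grp <- findInterval(nearest, sort(v) + 0.5) + 1L
          for (g in sort(unique(grp))) {
            gp <- spx[grp == g, , drop = FALSE]
            out[cbind(gp[, 1] + bb[1] - 1L, gp[, 2] + bb[3] - 1L)] <- nxt
            nxt <- nxt + 1L
          }
          assigned <- TRUE
        }
      } else {
        ## branched or wide fragment: check the transverse span
        ctr <- colMeans(px)
        X <- sweep(px, 2, ctr)
        eg <- eigen(crossprod(X) / nrow(px), symmetric = TRUE)
        tr <- X %*% eg$vectors[, 2]
        if (diff(quantile(tr, c(0.05, 0.95))) + 1 > 1.5 * wpx) {
          for (sgn in c(-1, 1)) {
            gp <- px[sgn * tr >= 0, , drop = FALSE]
            if (nrow(gp) > 0) { out[gp] <- nxt; nxt <- nxt + 1L }
          }
          assigned <- TRUE
        }
      }
    }
    if (!assigned) { out[px] <- nxt; nxt <- nxt + 1L }
  }
  out
}

#' Second-pass merge of sub-cell detections
#'
#' Candidate cells smaller than `frac` of the expected cell footprint
#' (CellLength x CellWidth in pixels) are merged into a touching neighbour
#' when the merged region passes the chain test: collinear, no deep valley
#' anywhere along it, median width within 1.5 cell widths. Among feasible
#' partners the max-solidity merge wins. A true small cell abutting a
#' neighbour keeps its septum cusp valley and is left alone.
#'
#' @param lab integer label matrix of candidate cells.
#' @param species a [species_config()].
#' @param t_valley deep-valley threshold.
#' @param frac fraction of the expected cell footprint below which a
#'   detection is a merge candidate.
#' @return relabelled matrix (compact ids).
#' @export
merge_subcell_detections <- function(lab, species, t_valley = 0.70,
                                     frac = 0.5) {
  wpx <- species$cell_width / species$cal_factor
  prune <- max(3, round(wpx))
  exp_area <- species$cell_length * species$cell_width / species$cal_factor^2
  repeat {
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) <= 1) break
    sizes <- vapply(ids, function(id) sum(lab == id), numeric(1))
    small <- ids[sizes < frac * exp_area]
    if (length(small) == 0) break
    pairs <- touching_pairs(lab)
    merged_any <- FALSE
    for (f in small[order(sizes[match(small, ids)])]) {
      nbrs <- unique(c(pairs[pairs[, 1] == f, 2], pairs[pairs[, 2] == f, 1]))
      if (length(nbrs) == 0) next
      best <- NULL
      for (g in sort(nbrs)) {
        mm <- lab == f | lab == g
        ## reuniting split halves stays within one cell footprint (cells
        ## just before division reach ~1.4x the expected mean footprint);
        ## merging into a whole neighbouring cell does not
        if (sum(mm) > 1.25 * exp_area) next
        bb <- grow_bbox(mask_bbox(mm), 2, dim(lab))
        sub <- crop_bbox(mm, bb)
        prof <- region_width_profile(sub, prune)
        if (is.null(prof) || is.null(prof$widths)) next
        if (median(prof$widths) > 1.5 * wpx) next
        if (length(find_deep_valleys(prof$widths, t_valley)) > 0) next
        sld <- solidity(which(mm, arr.ind = TRUE))
        if (is.null(best) || sld > best$s) best <- list(g = g, s = sld)
      }
      if (!is.null(best)) {
        lab[lab == f] <- best$g
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }
  ids <- sort(unique(lab[lab > 0]))
  matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
}

## Partition fragment ids into connected chunks of at most `max_size`
## fragments (BFS over the touching graph).
fragment_chunks <- function(lab, max_size = 10) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(list())
  prs <- touching_pairs(lab)
  adj <- lapply(setNames(ids, ids), function(i)
    sort(unique(c(prs[prs[, 1] == i, 2], prs[prs[, 2] == i, 1]))))
  unseen <- ids
  chunks <- list()
  while (length(unseen) > 0) {
    q <- unseen[1]
    chunk <- integer(0)
    while (length(q) > 0 && length(chunk) < max_size) {
      v <- q[1]; q <- q[-1]
      if (!(v %in% unseen)) next
      chunk <- c(chunk, v)
      unseen <- setdiff(unseen, v)
      q <- c(q, intersect(adj[[as.character(v)]], unseen))
    }
    chunks[[length(chunks) + 1L]] <- chunk
  }
  chunks
}

#' Merge undersized cell regions into touching neighbours
#'
#' Any region with area below `A` merges into the touching neighbour that
#' maximizes the post-merge solidity; isolated undersized regions are kept
#' and flagged. Iterates until stable.
#'
#' @param lab integer label matrix of candidate cell regions.
#' @param A minimum area in pixels (see [min_fragment_area()]).
#' @return list with `labels` and `undersized` (ids of retained sub-A
#'   isolated regions, under the output labelling).
#' @export
merge_small_fragments <- function(lab, A) {
  repeat {
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) <= 1) break
    sizes <- vapply(ids, function(id) sum(lab == id), numeric(1))
    small <- ids[sizes < A]
    if (length(small) == 0) break
    pairs <- touching_pairs(lab)
    merged_any <- FALSE
    for (f in small) {
      nbrs <- unique(c(pairs[pairs[, 1] == f, 2], pairs[pairs[, 2] == f, 1]))
      if (length(nbrs) == 0) next
      sol <- vapply(sort(nbrs), function(g)
        solidity(which(lab == f | lab == g, arr.ind = TRUE)), numeric(1))
      g <- sort(nbrs)[which.max(sol)]
      lab[lab == f] <- g
      merged_any <- TRUE
      break  # adjacency changed; recompute
    }
    if (!merged_any) break
  }
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
  sizes <- vapply(seq_along(ids), function(i) sum(out == i), numeric(1))
  list(labels = out, undersized = which(sizes < A))
}
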