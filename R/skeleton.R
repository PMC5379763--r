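## Morphological skeletonization (Zhang-Suen thinning), spur pruning,
## junction detection and centerline ordering. The skeleton drives the
## collinear/complex bifurcation of the segmentation method.

## Zhang-Suen thinning of a logical matrix; returns logical matrix.
skeletonize <- function(mask) {
  b <- mask > 0
  if (!any(b)) return(b)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      ## neighbours P2..P9 clockwise from north
      P <- list(mat_shift(b, 1, 0), mat_shift(b, 1, -1),  # P2=N, P3=NE
                mat_shift(b, 0, -1), mat_shift(b, -1, -1), # P4=E, P5=SE
                mat_shift(b, -1, 0), mat_shift(b, -1, 1),  # P6=S, P7=SW
                mat_shift(b, 0, 1), mat_shift(b, 1, 1))    # P8=W, P9=NW
      Bn <- Reduce(`+`, P)
      A <- matrix(0L, nrow(b), ncol(b))
      for (i in 1:8) {
        nxt <- P[[i %% 8 + 1]]
        A <- A + (!P[[i]] & nxt)
      }
      if (sub == 1) {
        c1 <- !(P[[1]] & P[[3]] & P[[5]])   # P2*P4*P6 = 0
        c2 <- !(P[[3]] & P[[5]] & P[[7]])   # P4*P6*P8 = 0
      } else {
        c1 <- !(P[[1]] & P[[3]] & P[[7]])   # P2*P4*P8 = 0
        c2 <- !(P[[1]] & P[[5]] & P[[7]])   # P2*P6*P8 = 0
      }
      del <- b & Bn >= 2 & Bn <= 6 & A == 1 & c1 & c2
      if (any(del)) { b <- b & !del; changed <- TRUE }
    }
    if (!changed) break
  }
  b
}

## skeleton pixels with >2 skeleton neighbours (junction points)
skeleton_junctions <- function(skel) {
  nb <- neighbor_count8(skel)
  which(skel & nb > 2, arr.ind = TRUE)
}

## Remove spur branches shorter than `prune_len` emanating from junctions.
## Branches are walked from each endpoint; a branch that reaches a junction
## within `prune_len` steps is deleted (the junction pixel is kept).
prune_spurs <- function(skel, prune_len) {
  if (prune_len < 1) return(skel)
  repeat {
    nb <- neighbor_count8(skel)
    jmask <- skel & nb > 2
    if (!any(jmask)) return(skel)
    ends <- which(skel & nb == 1, arr.ind = TRUE)
    if (nrow(ends) == 0) return(skel)
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      path <- walk_from(skel, ends[e, ], jmask, max_len = prune_len)
      if (!is.null(path$hit_junction) && path$hit_junction &&
          nrow(path$pixels) <= prune_len) {
        for (i in seq_len(nrow(path$pixels)))
          skel[path$pixels[i, 1], path$pixels[i, 2]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) return(skel)
  }
}

## Walk along a degree<=2 path from `start` until a junction, an end, or
## max_len steps. Returns visited pixels (excluding any junction pixel).
walk_from <- function(skel, start, jmask, max_len = Inf) {
  cur <- as.integer(start)
  prev <- c(NA_integer_, NA_integer_)
  path <- matrix(integer(0), 0, 2)
  steps <- 0
  repeat {
    path <- rbind(path, cur)
    steps <- steps + 1
    if (steps > max_len) return(list(pixels = path, hit_junction = FALSE))
    nbrs <- skeleton_neighbors(skel, cur)
    if (!is.na(prev[1]))
      nbrs <- nbrs[!(nbrs[, 1] == prev[1] & nbrs[, 2] == prev[2]), , drop = FALSE]
    if (nrow(nbrs) == 0) return(list(pixels = path, hit_junction = FALSE))
    jn <- jmask[nbrs]
    if (any(jn)) return(list(pixels = path, hit_junction = TRUE))
    if (nrow(nbrs) > 1) return(list(pixels = path, hit_junction = FALSE))
    prev <- cur
    cur <- as.integer(nbrs[1, ])
  }
}

skeleton_neighbors <- function(skel, p) {
  rs <- p[1] + (-1):1; cs <- p[2] + (-1):1
  rs <- rs[rs >= 1 & rs <= nrow(skel)]
  cs <- cs[cs >= 1 & cs <= ncol(skel)]
  sub <- which(skel[rs, cs, drop = FALSE], arr.ind = TRUE)
  out <- cbind(rs[sub[, 1]], cs[sub[, 2]])
  out[!(out[, 1] == p[1] & out[, 2] == p[2]), , drop = FALSE]
}

## Ordered centerline of a junction-free skeleton: walk from one endpoint.
## Returns a matrix of (row, col); NULL when the skeleton is degenerate
## (a cycle or a single pixel).
order_centerline <- function(skel) {
  nb <- neighbor_count8(skel)
  ends <- which(skel & nb <= 1, arr.ind = TRUE)
  npix <- sum(skel)
  if (npix == 0) return(NULL)
  if (npix == 1) return(which(skel, arr.ind = TRUE))
  if (nrow(ends) == 0) return(NULL)  # cycle
  ## start at the topmost-leftmost endpoint for determinism
  o <- order(ends[, 1], ends[, 2])
  start <- ends[o[1], ]
  jmask <- matrix(FALSE, nrow(skel), ncol(skel))
  path <- walk_from(skel, start, jmask, max_len = Inf)
  path$pixels
}

#' Classify a cell object as collinear or complex
#'
#' Computes the morphological skeleton of the object, prunes spur branches
#' shorter than one cell width (boundary-noise protection), and labels the
#' object `"complex"` when the pruned skeleton retains junction points
#' (pixels with more than two skeleton neighbours), `"collinear"` otherwise.
#' Degenerate objects (< 4 px) are collinear single-cell candidates.
#'
#' @param mask logical matrix, one 8-connected object.
#' @param prune_len spur-pruning length in pixels (about one cell width).
#' @return list with `klass` ("collinear"/"complex"), `skeleton` (logical
#'   matrix) and `junctions` (matrix of row/col positions).
#' @export
classify_object <- function(mask, prune_len = 5) {
  if (sum(mask) < 4) {
    return(list(klass = "collinear", skeleton = mask > 0,
                junctions = matrix(integer(0), 0, 2)))
  }
  skel <- skeletonize(mask)
  skel <- prune_spurs(skel, prune_len)
  jn <- skeleton_junctions(skel)
  list(klass = if (nrow(jn) > 0) "complex" else "collinear",
       skeleton = skel, junctions = jn)
}
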