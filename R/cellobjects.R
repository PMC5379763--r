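## From colony masks to "cell objects": adaptive thresholding, masking and
## connected-component extraction. A cell object is a set of touching cells;
## the union of objects covers the colony foreground and objects are
## pairwise disjoint.

#' Adaptive (local-mean) thresholding
#'
#' Per-pixel threshold is the local mean over a `window_px` square minus
#' `offset`. Foreground polarity follows the imaging modality: dark cells in
#' phase contrast / bright field fall below the threshold, fluorescent cells
#' rise above it.
#'
#' @param frame preprocessed intensity matrix in \[0, 1\].
#' @param window_px odd window size in pixels (about twice the expected cell
#'   length).
#' @param offset threshold offset as a fraction of dynamic range.
#' @param cells `"dark"` or `"bright"`.
#' @param clamp_level optional global cell/background threshold (e.g. the
#'   Otsu level of the colony region). The per-pixel threshold never crosses
#'   it, so background-dominated neighbourhoods (small colonies) cannot
#'   drag the local threshold into the between-cell boundary intensities.
#' @return logical foreground matrix.
#' @export
adaptive_threshold <- function(frame, window_px, offset = 0.02,
                               cells = c("dark", "bright"),
                               clamp_level = NULL) {
  cells <- match.arg(cells)
  window_px <- as.integer(window_px)
  if (window_px %% 2 == 0) window_px <- window_px + 1L
  if (window_px >= min(dim(frame)))
    stop("adaptive threshold window must be smaller than the frame")
  mu <- box_mean(frame, window_px)
  if (cells == "dark") {
    thr <- mu - offset
    if (!is.null(clamp_level)) thr <- pmin(thr, clamp_level)
    frame < thr
  } else {
    thr <- mu + offset
    if (!is.null(clamp_level)) thr <- pmax(thr, clamp_level)
    frame > thr
  }
}

## Otsu threshold of an intensity sample (256-bin histogram maximizing
## inter-class variance)
otsu_level <- function(vals, bins = 256) {
  vals <- vals[is.finite(vals)]
  h <- hist(vals, breaks = seq(min(vals), max(vals), length.out = bins + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  om <- cumsum(p); mu <- cumsum(p * h$mids)
  mt <- mu[length(mu)]
  sb <- (mt * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- 0
  h$mids[which.max(sb)]
}

#' Intersect a binary image with a colony mask
#'
#' Logical AND removing the salt-and-pepper artifacts that adaptive
#' thresholding produces outside colony regions.
#'
#' @param binary logical or 0/1 matrix.
#' @param colony_mask logical or 0/1 matrix of the same shape.
#' @return logical matrix.
#' @export
mask_multiply <- function(binary, colony_mask) {
  stopifnot(all(dim(binary) == dim(colony_mask)))
  (binary > 0) & (colony_mask > 0)
}

#' Extract cell objects from a colony-masked binary image
#'
#' 8-connected components; the partition property (union covers the
#' foreground, pairwise disjoint) holds by construction.
#'
#' @param binary logical matrix of in-colony foreground.
#' @return list of objects, each a list with `mask` (full-frame logical
#'   matrix), `pixels` (row/col matrix) and `bbox`.
#' @export
extract_cell_objects <- function(binary) {
  lab <- label_components(binary)
  ids <- seq_len(max(lab))
  lapply(ids, function(id) {
    m <- lab == id
    list(mask = m, pixels = which(m, arr.ind = TRUE), bbox = mask_bbox(m))
  })
}
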