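## User-facing configuration. The pipeline needs only the spatial
## calibration, the imaging modality, and the species' expected cell length
## and width; everything else is derived or has validated defaults.

#' Species / imaging configuration
#'
#' @param cell_length expected cell length in um (e.g. 3.5 for
#'   *S.* Typhimurium).
#' @param cell_width expected cell width in um (e.g. 1.1).
#' @param cal_factor spatial calibration, um/pixel.
#' @param modality imaging modality tag.
#' @return object of class `species_config`.
#' @export
species_config <- function(cell_length = 3.5, cell_width = 1.1,
                           cal_factor = 0.125,
                           modality = c("phase-contrast", "bright-field",
                                        "fluorescence")) {
  modality <- match.arg(modality)
  stopifnot(cell_length >= cell_width, cell_width > 0, cal_factor > 0)
  structure(list(cell_length = cell_length, cell_width = cell_width,
                 cal_factor = cal_factor, modality = modality),
            class = "species_config")
}

#' Segmentation tuning parameters
#'
#' @param t_valley deep-valley threshold T in (0, 1); the physically
#'   meaningful range is \[0.65, 0.75\].
#' @param point_sigma2 variance of the per-pixel point generator (kept below
#'   0.5, the half-distance between neighbouring pixels).
#' @param adaptive_window_px local-mean window for adaptive thresholding
#'   (odd; default 2 x cell length in pixels, set at run time).
#' @param adaptive_offset adaptive threshold offset (fraction of range).
#' @param rng_seed seed making segmentation bit-for-bit reproducible.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(t_valley = 0.70, point_sigma2 = 0.3,
                                adaptive_window_px = NULL,
                                adaptive_offset = 0.02, rng_seed = 1L) {
  stopifnot(t_valley > 0, t_valley < 1, point_sigma2 > 0, point_sigma2 < 0.5)
  structure(list(t_valley = t_valley, point_sigma2 = point_sigma2,
                 adaptive_window_px = adaptive_window_px,
                 adaptive_offset = adaptive_offset,
                 rng_seed = as.integer(rng_seed)),
            class = "segmentation_config")
}

#' Estimate the deep-valley threshold T from a pre-division frame
#'
#' T is the ratio of the minimum to the maximum width of the largest
#' collinear object in a frame preceding the first division, clamped to
#' \[0.65, 0.75\]. Falls back to the 0.70 default when no suitable object
#' exists.
#'
#' @param binary in-colony foreground of a pre-first-division frame.
#' @param species a [species_config()].
#' @return scalar T.
#' @export
estimate_t_valley <- function(binary, species) {
  objs <- extract_cell_objects(binary)
  if (length(objs) == 0) return(0.70)
  areas <- vapply(objs, function(o) nrow(o$pixels), numeric(1))
  prune <- max(3, round(species$cell_width / species$cal_factor))
  o <- objs[[which.max(areas)]]
  cls <- classify_object(o$mask, prune_len = prune)
  if (cls$klass != "collinear") return(0.70)
  curve <- distance_curve(o$mask, order_centerline(cls$skeleton))
  if (is.null(curve)) return(0.70)
  ## interior widths only: pole caps taper to zero by construction
  w <- curve$widths
  n <- length(w)
  trim <- max(1, round(n * 0.15))
  w <- w[trim:(n - trim + 1)]
  if (length(w) < 3 || max(w) <= 0) return(0.70)
  clamp(min(w) / max(w), 0.65, 0.75)
}
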