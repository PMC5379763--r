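## Frame loading, denoising and contrast enhancement.

#' Load a calibrated frame stack
#'
#' Reads a multi-page TIFF or a directory of TIFF/PNG frames (lexicographic
#' file order = time order). Intensities are normalized to \[0, 1\]; an
#' optional fluorescence channel is loaded in parallel and never preprocessed
#' so that downstream measurements stay raw.
#'
#' @param path multi-page TIFF file or frame directory.
#' @param cal_factor spatial calibration in um/pixel.
#' @param sampling_period frame interval in minutes.
#' @param modality imaging modality tag: `"phase-contrast"`, `"bright-field"`
#'   or `"fluorescence"`.
#' @param fluorescence optional path to a parallel fluorescence channel.
#' @return object of class `frame_stack`: list with `frames`, `cal_factor`,
#'   `sampling_period`, `modality`, `fluorescence_frames`.
#' @export
load_frames <- function(path, cal_factor, sampling_period,
                        modality = c("phase-contrast", "bright-field",
                                     "fluorescence"),
                        fluorescence = NULL) {
  modality <- match.arg(modality)
  stopifnot(cal_factor > 0, sampling_period > 0)
  frames <- read_image_sequence(path)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1)
    stop("inconsistent frame shapes in ", path)
  fl <- if (!is.null(fluorescence)) read_image_sequence(fluorescence) else NULL
  structure(list(frames = frames, cal_factor = cal_factor,
                 sampling_period = sampling_period, modality = modality,
                 fluorescence_frames = fl),
            class = "frame_stack")
}

read_image_sequence <- function(path) {
  read_one <- function(f) {
    m <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
         else tiff::readTIFF(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no TIFF/PNG frames found in ", path)
    lapply(files, read_one)
  } else if (file.exists(path)) {
    m <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(m)) m <- list(m)
    lapply(m, function(x) if (length(dim(x)) == 3) x[, , 1] else x)
  } else stop("input not found: ", path)
}

## -------------------------------------------------------------------------
## a-trous (starlet) stationary wavelet shrinkage

## One separable B3-spline smoothing pass with holes of spacing 2^(j-1).
atrous_smooth <- function(m, step) {
  k <- c(1, 4, 6, 4, 1) / 16
  offs <- c(-2, -1, 0, 1, 2) * step
  smooth_dim <- function(mm, along_rows) {
    acc <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_along(offs)) {
      acc <- acc + k[i] * (if (along_rows) mat_shift_replicate(mm, offs[i], 0)
                           else mat_shift_replicate(mm, 0, offs[i]))
    }
    acc
  }
  smooth_dim(smooth_dim(m, TRUE), FALSE)
}

## shift with replicate (edge-clamped) padding
mat_shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- clamp(seq_len(nr) - dr, 1, nr)
  ci <- clamp(seq_len(nc) - dc, 1, nc)
  m[ri, ci, drop = FALSE]
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Denoise a frame
#'
#' Default backend is an a-trous (starlet) stationary wavelet decomposition
#' with BayesShrink soft thresholding per detail level: the noise sd is
#' estimated from the median absolute deviation of the finest detail band,
#' and each band is shrunk by `sigma_n^2 / sigma_x` where `sigma_x` is the
#' estimated signal sd in the band. Edge-preserving: strong edges carry
#' coefficients far above the threshold and survive shrinkage.
#'
#' @param frame numeric intensity matrix (finite values).
#' @param method `"wavelet"` (default) or `"none"` (identity; useful to slot
#'   an external denoiser into the pipeline contract).
#' @param levels number of decomposition levels.
#' @return denoised matrix, same shape.
#' @export
denoise <- function(frame, method = "wavelet", levels = 3) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  if (method == "none") return(frame)
  if (method != "wavelet") stop("unknown denoise method: ", method)
  c_prev <- frame
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    c_next <- atrous_smooth(c_prev, 2^(j - 1))
    details[[j]] <- c_prev - c_next
    c_prev <- c_next
  }
  sigma_n <- median(abs(details[[1]])) / 0.6745
  out <- c_prev
  for (j in seq_len(levels)) {
    w <- details[[j]]
    sigma_j <- sigma_n / 2^(j - 1)          # noise decays across starlet levels
    sigma_x <- sqrt(max(mean(w^2) - sigma_j^2, 1e-12))
    thr <- sigma_j^2 / sigma_x
    out <- out + soft_threshold(w, thr)
  }
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Thin wrapper around [EBImage::clahe()] enforcing the pipeline's contract:
#' input in \[0, 1\], output in \[0, 1\], tile grid validated against the
#' frame size. Used to sharpen cell edges and suppress luminous local
#' colony background.
#'
#' @param frame numeric matrix in \[0, 1\].
#' @param clip_limit normalized clipping limit.
#' @param tiles c(rows, cols) tile grid.
#' @return equalized matrix in \[0, 1\].
#' @export
enhance_contrast <- function(frame, clip_limit = 0.01, tiles = c(8, 8)) {
  stopifnot(is.matrix(frame), min(frame) >= 0, max(frame) <= 1)
  if (tiles[1] > nrow(frame) || tiles[2] > ncol(frame))
    stop("tile grid larger than frame")
  if (max(frame) - min(frame) < 1e-9) return(frame)  # uniform frame: identity
  ## pad to a multiple of the tile grid (edge replication), crop afterwards
  nr <- nrow(frame); nc <- ncol(frame)
  nr2 <- ceiling(nr / tiles[1]) * tiles[1]
  nc2 <- ceiling(nc / tiles[2]) * tiles[2]
  padded <- frame[c(seq_len(nr), rep(nr, nr2 - nr)),
                  c(seq_len(nc), rep(nc, nc2 - nc)), drop = FALSE]
  out <- EBImage::clahe(EBImage::Image(padded), nx = as.integer(tiles[2]),
                        ny = as.integer(tiles[1]), limit = clip_limit * 100)
  clamp(matrix(as.numeric(EBImage::imageData(out)), nr2, nc2)[seq_len(nr),
                                                              seq_len(nc)],
        0, 1)
}

#' Preprocess every frame of a stack
#'
#' Applies [denoise()] then [enhance_contrast()] exactly once per frame
#' (shape and calibration metadata preserved). The fluorescence channel, if
#' present, is left untouched.
#'
#' @param stack a [load_frames()] result (or any list with `frames`).
#' @param denoise_method passed to [denoise()].
#' @param clip_limit,tiles passed to [enhance_contrast()].
#' @return the stack with preprocessed `frames`.
#' @export
preprocess_stack <- function(stack, denoise_method = "wavelet",
                             clip_limit = 0.01, tiles = c(8, 8)) {
  stack$frames <- lapply(stack$frames, function(f)
    enhance_contrast(clamp(denoise(f, method = denoise_method), 0, 1),
                     clip_limit = clip_limit, tiles = tiles))
  stack
}
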