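## Synthetic cell-movie generator with exact ground truth.
##
## Rod-shaped (spherocylindrical) cells elongate exponentially, constrict into
## a "bow tie" just before division, split ~50/50, and are packed by iterative
## pairwise repulsion so that colonies stay dense with touching cells, the
## regime the segmentation pipeline is built for. Rendering mimics
## phase-contrast (dark cells, bright halo), bright-field, or a
## fluorescence-like modality, with PSF blur, additive Gaussian noise and a
## multiplicative illumination gradient. Every frame comes with an exact
## integer label mask plus lineage and colony tables.

#' Parameters for the synthetic cell-movie generator
#'
#' Defaults describe a dense multi-colony phase-contrast movie of a
#' rod-shaped organism resembling *Salmonella* Typhimurium: 1.1 um cell
#' width, division near 5 um, 25-min doubling time, 0.125 um/pixel at a
#' 5-min sampling period, three founder cells seeding three micro-colonies.
#' Elongation rate and division length are gamma-distributed across cells.
#'
#' @param seed integer seed; the single RNG stream for all stochastic draws.
#' @param cal_factor spatial calibration, um per pixel.
#' @param sampling_period frame interval in minutes.
#' @param n_frames number of frames to simulate.
#' @param field_px image size, c(rows, cols).
#' @param n_founders number of founder cells (= initial colonies).
#' @param founder_positions `"random"` or an `n_founders` x 2 matrix of
#'   (x, y) positions in um.
#' @param k_mean,k_cv mean and coefficient of variation of the per-cell
#'   elongation rate (1/min), gamma-distributed.
#' @param division_length_mean,division_length_cv gamma distribution of the
#'   tip-to-tip length (um) at which a cell divides.
#' @param width_um cell width (um).
#' @param constriction_depth septum width as a fraction of the full width,
#'   rendered over the middle 15% of the centerline in the pre-division frame.
#' @param division_jitter half-range of the daughter length-split asymmetry.
#' @param psf_sigma Gaussian point-spread sigma in pixels.
#' @param noise_sigma additive Gaussian noise sd, as fraction of dynamic range.
#' @param illumination_gradient peak-to-centre relative amplitude of a linear
#'   multiplicative illumination field.
#' @param modality `"phase-contrast"`, `"bright-field"` or `"fluorescence"`.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       cal_factor = 0.125,
                       sampling_period = 5,
                       n_frames = 40L,
                       field_px = c(560L, 560L),
                       n_founders = 3L,
                       founder_positions = "random",
                       k_mean = log(2) / 25,
                       k_cv = 0.15,
                       division_length_mean = 5.0,
                       division_length_cv = 0.07,
                       width_um = 1.1,
                       constriction_depth = 0.6,
                       division_jitter = 0.02,
                       psf_sigma = 1,
                       noise_sigma = 0.05,
                       illumination_gradient = 0.1,
                       modality = c("phase-contrast", "bright-field", "fluorescence")) {
  modality <- match.arg(modality)
  p <- list(seed = as.integer(seed), cal_factor = cal_factor,
            sampling_period = sampling_period, n_frames = as.integer(n_frames),
            field_px = as.integer(field_px), n_founders = as.integer(n_founders),
            founder_positions = founder_positions,
            k_mean = k_mean, k_cv = k_cv,
            division_length_mean = division_length_mean,
            division_length_cv = division_length_cv,
            width_um = width_um, constriction_depth = constriction_depth,
            division_jitter = division_jitter, psf_sigma = psf_sigma,
            noise_sigma = noise_sigma,
            illumination_gradient = illumination_gradient, modality = modality)
  stopifnot(p$cal_factor > 0, p$sampling_period > 0, p$n_frames >= 1,
            all(p$field_px >= 16), p$n_founders >= 1,
            p$k_mean > 0, p$k_cv >= 0,
            p$division_length_mean > p$width_um,
            p$constriction_depth > 0, p$constriction_depth < 1,
            p$noise_sigma >= 0)
  class(p) <- "sim_params"
  p
}

## gamma draw parameterized by mean and CV; CV = 0 degenerates to the mean.
rgamma_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

## -------------------------------------------------------------------------
## cell-state table helpers

new_cell_row <- function(cell_id, parent_id, colony, cx, cy, phi, l0,
                         birth_time, k, div_len, width) {
  data.frame(cell_id = cell_id, parent_id = parent_id, colony = colony,
             cx = cx, cy = cy, phi = phi, l0 = l0, birth_time = birth_time,
             k = k, div_len = div_len, width = width)
}

## Resolve overlaps by symmetric repulsion along the closest-approach normal.
relax_overlaps <- function(cells, lengths, tol_frac = 0.05, max_iter = 80) {
  n <- nrow(cells)
  if (n < 2) return(cells)
  w <- cells$width
  for (iter in seq_len(max_iter)) {
    moved <- FALSE
    ## candidate pairs by centre distance
    cd <- as.matrix(stats::dist(cbind(cells$cx, cells$cy)))
    reach <- outer(lengths, lengths, `+`) / 2 + max(w)
    pairs <- which(cd < reach & upper.tri(cd), arr.ind = TRUE)
    if (nrow(pairs) == 0) break
    for (pidx in seq_len(nrow(pairs))) {
      i <- pairs[pidx, 1]; j <- pairs[pidx, 2]
      ai <- cell_axis(c(cells$cx[i], cells$cy[i]), cells$phi[i], lengths[i], w[i])
      aj <- cell_axis(c(cells$cx[j], cells$cy[j]), cells$phi[j], lengths[j], w[j])
      ss <- segment_segment_distance(ai$p1, ai$p2, aj$p1, aj$p2)
      pen <- (w[i] + w[j]) / 2 - ss$dist
      if (pen > tol_frac * min(w[i], w[j])) {
        shift <- pen / 2
        cells$cx[i] <- cells$cx[i] - ss$dir[1] * shift
        cells$cy[i] <- cells$cy[i] - ss$dir[2] * shift
        cells$cx[j] <- cells$cx[j] + ss$dir[1] * shift
        cells$cy[j] <- cells$cy[j] + ss$dir[2] * shift
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  cells
}

## Rasterize cells into a label mask (0 background). Ties go to the cell whose
## boundary is deepest at the pixel. Returns integer matrix.
rasterize_cells <- function(cells, lengths, constricted, params) {
  nr <- params$field_px[1]; nc <- params$field_px[2]
  cal <- params$cal_factor
  lab <- matrix(0L, nr, nc)
  depth <- matrix(-Inf, nr, nc)
  for (i in seq_len(nrow(cells))) {
    L <- lengths[i]; w <- cells$width[i]
    ax <- cell_axis(c(cells$cx[i], cells$cy[i]), cells$phi[i], L, w)
    pad <- w / 2 + 2 * cal
    r1 <- max(1L, floor((min(ax$p1[2], ax$p2[2]) - pad) / cal))
    r2 <- min(nr, ceiling((max(ax$p1[2], ax$p2[2]) + pad) / cal))
    c1 <- max(1L, floor((min(ax$p1[1], ax$p2[1]) - pad) / cal))
    c2 <- min(nc, ceiling((max(ax$p1[1], ax$p2[1]) + pad) / cal))
    if (r1 > r2 || c1 > c2) next
    rr <- r1:r2; cc <- c1:c2
    gx <- rep((cc - 0.5) * cal, each = length(rr))
    gy <- rep((rr - 0.5) * cal, times = length(cc))
    pr <- point_segment_distance(gx, gy, ax$p1, ax$p2)
    hw <- rep(w / 2, length(gx))
    if (constricted[i]) {
      ## septum: linear taper to constriction_depth over middle 15% of axis
      s <- abs(pr$t - 0.5)
      band <- s < 0.075
      f <- params$constriction_depth +
        (1 - params$constriction_depth) * (s[band] / 0.075)
      hw[band] <- hw[band] * f
    }
    dv <- hw - pr$dist
    sel <- dv > 0
    if (!any(sel)) next
    dmat <- matrix(dv, length(rr), length(cc))
    smat <- matrix(sel, length(rr), length(cc))
    sub_d <- depth[rr, cc, drop = FALSE]
    win <- smat & (dmat > sub_d)
    if (any(win)) {
      sub_l <- lab[rr, cc, drop = FALSE]
      sub_l[win] <- cells$cell_id[i]
      sub_d[win] <- dmat[win]
      lab[rr, cc] <- sub_l
      depth[rr, cc] <- sub_d
    }
  }
  lab
}

render_intensity <- function(label, params) {
  fg <- label > 0
  levels <- switch(params$modality,
    "phase-contrast" = c(bg = 0.75, cell = 0.30, halo = 0.92, iface = 0.52),
    "bright-field"   = c(bg = 0.70, cell = 0.45, halo = NA, iface = 0.60),
    "fluorescence"   = c(bg = 0.05, cell = 0.80, halo = NA, iface = 0.35))
  img <- matrix(levels["bg"], nrow(label), ncol(label))
  img[fg] <- levels["cell"]
  ## cell-cell interfaces scatter light and appear at an intermediate level
  ## (the cue adaptive thresholding uses in real dense colonies)
  iface <- matrix(FALSE, nrow(label), ncol(label))
  for (sh in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    nb <- mat_shift(label, sh[1], sh[2], fill = 0L)
    iface <- iface | (fg & nb > 0 & nb != label)
  }
  img[iface] <- levels["iface"]
  if (!is.na(levels["halo"])) {
    halo <- EBImage::dilate(EBImage::Image(fg * 1), disc_brush(2)) > 0.5
    halo <- matrix(halo, nrow(label), ncol(label)) & !fg
    img[halo] <- levels["halo"]
  }
  g <- params$illumination_gradient
  if (g != 0) {
    grad <- matrix(rep(seq_len(ncol(img)) / ncol(img) - 0.5, each = nrow(img)),
                   nrow(img), ncol(img))
    img <- img * (1 + g * grad)
  }
  if (params$psf_sigma > 0) img <- gauss_blur(img, params$psf_sigma)
  if (params$noise_sigma > 0)
    img <- img + matrix(rnorm(length(img), 0, params$noise_sigma),
                        nrow(img), ncol(img))
  clamp(img, 0, 1)
}

#' Simulate a synthetic cell movie with exact ground truth
#'
#' Deterministic given `params` (identical parameters give a bit-identical
#' movie). Cells elongate as `l(t) = l0 * exp(k t)`, divide at their sampled
#' division length into two daughters splitting the length ~50/50, and are
#' relaxed by pairwise repulsion to keep spherocylinder overlap below 5% of
#' the cell width. If a colony reaches the image border the simulation is
#' truncated at that frame and flagged.
#'
#' @param params a [sim_params()] object.
#' @return object of class `sim_movie` with elements `frames` (list of
#'   intensity matrices in \[0,1\]), `label_masks` (list of integer matrices,
#'   0 = background), `lineage_truth` (data.frame parent_id, child_id,
#'   division_frame), `colony_truth` (data.frame frame, cell_id, colony_id),
#'   `colony_merges` (data.frame frame, colony_a, colony_b), `cells`
#'   (per-cell ground-truth life table) and `params`; plus a `truncated` flag.
#' @export
simulate_movie <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  cal <- params$cal_factor
  fw <- params$field_px[2] * cal; fh <- params$field_px[1] * cal
  nf <- params$n_founders

  if (is.character(params$founder_positions)) {
    if (nf == 1) {
      pos <- matrix(c(fw / 2, fh / 2), 1, 2)
    } else {
      rad <- 0.24 * min(fw, fh)
      ang <- 2 * pi * seq_len(nf) / nf + runif(1, 0, 2 * pi)
      pos <- cbind(fw / 2 + rad * cos(ang), fh / 2 + rad * sin(ang))
    }
  } else {
    pos <- params$founder_positions
    stopifnot(is.matrix(pos), nrow(pos) == nf)
  }

  k0 <- rgamma_mean_cv(nf, params$k_mean, params$k_cv)
  dl0 <- rgamma_mean_cv(nf, params$division_length_mean, params$division_length_cv)
  l_start <- dl0 * 2^(-runif(nf))          # random cell-cycle phase
  cells <- new_cell_row(seq_len(nf), NA_integer_, seq_len(nf),
                        pos[, 1], pos[, 2], runif(nf, 0, pi),
                        l_start, 0, k0, dl0, params$width_um)
  next_id <- nf + 1L

  frames <- vector("list", params$n_frames)
  masks <- vector("list", params$n_frames)
  lineage <- list(); colony_truth <- list(); merges <- list()
  divided <- data.frame(cell_id = integer(), division_frame = integer(),
                        division_length = numeric(),
                        sampled_division_length = numeric())
  truncated <- FALSE
  n_done <- 0L

  for (f in seq_len(params$n_frames)) {
    t_now <- (f - 1) * params$sampling_period
    len_at <- function(df, t) df$l0 * exp(df$k * (t - df$birth_time))

    ## divisions due at this frame
    repeat {
      lens <- len_at(cells, t_now)
      due <- which(lens >= cells$div_len)
      if (length(due) == 0) break
      for (i in due) {
        L <- lens[i]
        frac <- 0.5 + runif(1, -params$division_jitter, params$division_jitter)
        la <- frac * L; lb <- (1 - frac) * L
        dx <- cos(cells$phi[i]); dy <- sin(cells$phi[i])
        jit <- rnorm(2, 0, 0.03)
        kd <- rgamma_mean_cv(2, params$k_mean, params$k_cv)
        dld <- rgamma_mean_cv(2, params$division_length_mean,
                              params$division_length_cv)
        ida <- next_id; idb <- next_id + 1L
        next_id <- next_id + 2L
        kids <- rbind(
          new_cell_row(ida, cells$cell_id[i], cells$colony[i],
                       cells$cx[i] - dx * (L - la) / 2,
                       cells$cy[i] - dy * (L - la) / 2,
                       cells$phi[i] + jit[1], la, t_now, kd[1], dld[1],
                       params$width_um),
          new_cell_row(idb, cells$cell_id[i], cells$colony[i],
                       cells$cx[i] + dx * (L - lb) / 2,
                       cells$cy[i] + dy * (L - lb) / 2,
                       cells$phi[i] + jit[2], lb, t_now, kd[2], dld[2],
                       params$width_um))
        lineage[[length(lineage) + 1L]] <-
          data.frame(parent_id = cells$cell_id[i],
                     child_id = c(ida, idb), division_frame = f)
        divided <- rbind(divided,
                         data.frame(cell_id = cells$cell_id[i],
                                    division_frame = f, division_length = L,
                                    sampled_division_length = cells$div_len[i]))
        cells <- rbind(cells[-i, , drop = FALSE], kids)
        break  # re-scan: indices changed
      }
    }

    lens <- len_at(cells, t_now)
    cells <- relax_overlaps(cells, lens)

    ## border check (tip within 2 px of the field edge)
    tips <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      ax <- cell_axis(c(cells$cx[i], cells$cy[i]), cells$phi[i],
                      lens[i], cells$width[i])
      rbind(ax$p1, ax$p2)
    }))
    marg <- cells$width[1] / 2 + 2 * cal
    if (any(tips[, 1] < marg | tips[, 1] > fw - marg |
            tips[, 2] < marg | tips[, 2] > fh - marg)) {
      truncated <- TRUE
      break
    }

    ## septum on cells that will have divided by the next frame
    lens_next <- len_at(cells, t_now + params$sampling_period)
    constricted <- lens_next >= cells$div_len

    lab <- rasterize_cells(cells, lens, constricted, params)
    frames[[f]] <- render_intensity(lab, params)
    masks[[f]] <- lab
    colony_truth[[f]] <- data.frame(frame = f, cell_id = cells$cell_id,
                                    colony_id = cells$colony)

    ## colony-merge detection: masks of two colonies touching (8-adjacency)
    if (nf > 1) {
      cmap <- matrix(0L, nrow(lab), ncol(lab))
      idx <- match(lab[lab > 0], cells$cell_id)
      cmap[lab > 0] <- cells$colony[idx]
      cols_present <- sort(unique(cells$colony))
      if (length(cols_present) > 1) {
        for (a_i in seq_along(cols_present)) for (b_i in seq_along(cols_present)) {
          if (a_i >= b_i) next
          a <- cols_present[a_i]; b <- cols_present[b_i]
          ma <- EBImage::dilate(EBImage::Image((cmap == a) * 1), disc_brush(1)) > 0.5
          if (any(ma & (cmap == b))) {
            merges[[length(merges) + 1L]] <-
              data.frame(frame = f, colony_a = a, colony_b = b)
          }
        }
      }
    }
    n_done <- f
  }

  empty_lin <- data.frame(parent_id = integer(), child_id = integer(),
                          division_frame = integer())
  out <- list(
    frames = frames[seq_len(n_done)],
    label_masks = masks[seq_len(n_done)],
    lineage_truth = if (length(lineage)) do.call(rbind, lineage) else empty_lin,
    colony_truth = do.call(rbind, colony_truth),
    colony_merges = if (length(merges)) unique(do.call(rbind, merges)) else
      data.frame(frame = integer(), colony_a = integer(), colony_b = integer()),
    cells = cells,
    divided = divided,
    truncated = truncated,
    params = params)
  ## keep lineage rows only for divisions inside the rendered window
  out$lineage_truth <- out$lineage_truth[out$lineage_truth$division_frame <= n_done, ]
  class(out) <- "sim_movie"
  out
}

#' @export
print.sim_movie <- function(x, ...) {
  cat(sprintf("sim_movie: %d frames %dx%d px, %.3f um/px, %d cells final frame%s\n",
              length(x$frames), x$params$field_px[1], x$params$field_px[2],
              x$params$cal_factor,
              sum(x$colony_truth$frame == length(x$frames)),
              if (x$truncated) " (truncated at border)" else ""))
  invisible(x)
}

#' Ground-truth per-colony cell counts for one frame
#'
#' @param movie a [simulate_movie()] result.
#' @param frame 1-based frame index.
#' @return data.frame with columns `colony_id`, `cell_count`.
#' @export
ground_truth_counts <- function(movie, frame) {
  stopifnot(inherits(movie, "sim_movie"),
            frame >= 1, frame <= length(movie$frames))
  ct <- movie$colony_truth[movie$colony_truth$frame == frame, ]
  out <- aggregate(cell_id ~ colony_id, data = ct, FUN = function(z) length(unique(z)))
  names(out) <- c("colony_id", "cell_count")
  out[order(out$colony_id), ]
}

## -------------------------------------------------------------------------
## external interfaces: TIFF frames + masks, CSV truth, key=value params

#' Write a simulated movie to disk
#'
#' Frames and label masks go to multi-page 16-bit TIFF, lineage and colony
#' truth to CSV, parameters to a flat key=value config file.
#'
#' @param movie a `sim_movie`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_movie <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(lapply(movie$frames, function(m) clamp(m, 0, 1)),
                  file.path(dir, "frames.tif"), bits.per.sample = 16)
  tiff::writeTIFF(lapply(movie$label_masks, function(m) m / 65535),
                  file.path(dir, "label_masks.tif"), bits.per.sample = 16)
  write.csv(movie$lineage_truth, file.path(dir, "lineage_truth.csv"),
            row.names = FALSE)
  write.csv(movie$colony_truth, file.path(dir, "colony_truth.csv"),
            row.names = FALSE)
  write_config(movie$params[setdiff(names(movie$params), "founder_positions")],
               file.path(dir, "params.cfg"))
  invisible(dir)
}

#' Write/read a flat key=value configuration file
#' @param config named list of scalars (numeric, integer, character, logical).
#' @param path file path.
#' @return `read_config` returns a named list with types restored by
#'   `type.convert`.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) paste(format(v, digits = 17), collapse = ","),
                 character(1))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(p) {
    v <- strsplit(trimws(p[2]), ",", fixed = TRUE)[[1]]
    utils::type.convert(v, as.is = TRUE)
  })
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}
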