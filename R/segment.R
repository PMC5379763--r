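## Frame-level segmentation orchestration: colonies are processed
## independently (divide-and-conquer); inside each colony the foreground is
## partitioned into cell objects which take the collinear or the complex
## route depending on their skeleton, and the resulting cell regions are
## cleaned by the minimum-fragment-area rule and measured.

#' Segment all cells of one frame
#'
#' Pipeline per colony: adaptive thresholding, colony-mask multiplication,
#' cell-object extraction, skeleton classification, deep-valley splitting of
#' collinear objects / watershed + puzzle solving + MML-GMM refinement of
#' complex objects, small-fragment cleanup, geometry extraction. A failing
#' object is quarantined with a warning and never aborts the frame.
#'
#' @param frame preprocessed intensity matrix in \[0, 1\].
#' @param colony_label integer colony label matrix ([build_colony_mask()]).
#' @param species a [species_config()].
#' @param config a [segmentation_config()].
#' @param frame_idx 1-based frame number (reported and used for seeding).
#' @param fluor_frame optional raw fluorescence frame for intensity sums.
#' @return list with `cells` (data.frame: one row per segmented cell:
#'   colony_id, centroid, area, length/width in um, orientation, distance
#'   to colony centroid, fluorescence, on_colony_boundary, undersized) and
#'   `label` (integer matrix of cell-instant labels = row numbers).
#' @export
segment_frame <- function(frame, colony_label, species, config = segmentation_config(),
                          frame_idx = 1L, fluor_frame = NULL) {
  cal <- species$cal_factor
  wpx <- species$cell_width / cal
  prune <- max(3, round(wpx))
  A <- min_fragment_area(species)
  win <- config$adaptive_window_px %||%
    (2 * round(species$cell_length / cal) + 1)
  polarity <- if (species$modality == "fluorescence") "bright" else "dark"

  out_label <- matrix(0L, nrow(frame), ncol(frame))
  cells_list <- list()
  next_cell <- 1L
  colony_ids <- sort(unique(colony_label[colony_label > 0]))

  for (cid in colony_ids) {
    cmask <- colony_label == cid
    bb <- grow_bbox(mask_bbox(cmask), 2, dim(frame))
    ## local threshold clamped at the colony's cell/background Otsu level
    lvl <- otsu_level(frame[cmask])
    fg_col <- adaptive_threshold(frame, win, config$adaptive_offset, polarity,
                                 clamp_level = lvl)
    sub_fg <- despur_binary(crop_bbox(mask_multiply(fg_col, cmask), bb))
    ## conservative cell cores: cell-width-scale window and a stiffer
    ## offset; their connected components seed the complex-object
    ## watershed. A second, stiffer level resolves cores that the first
    ## level leaves fused.
    win_core <- 2 * round(0.75 * species$cell_width / cal) + 1
    fg_core <- adaptive_threshold(frame, win_core,
                                  2.5 * config$adaptive_offset, polarity,
                                  clamp_level = lvl)
    sub_core <- crop_bbox(mask_multiply(fg_core, cmask), bb)
    fg_core2 <- adaptive_threshold(frame, win_core,
                                   4 * config$adaptive_offset, polarity,
                                   clamp_level = lvl)
    sub_core2 <- crop_bbox(mask_multiply(fg_core2, cmask), bb)
    if (!any(sub_fg)) next
    ccent <- colMeans(which(cmask, arr.ind = TRUE))
    ## colony-boundary band: pixels of the colony mask near its edge
    cmask_sub <- crop_bbox(cmask, bb)
    interior <- EBImage::erode(EBImage::Image(cmask_sub * 1),
                               disc_brush(max(2, round(wpx / 2)))) > 0.5
    boundary_band <- cmask_sub & !matrix(interior, nrow(cmask_sub), ncol(cmask_sub))

    lab_sub <- matrix(0L, nrow(sub_fg), ncol(sub_fg))
    next_part <- 1L
    objs <- extract_cell_objects(sub_fg)
    for (oi in seq_along(objs)) {
      obj <- objs[[oi]]
      res <- tryCatch(
        segment_object(obj, species, config, prune,
                       seed = derive_seed(config$rng_seed,
                                          frame_idx * 1299709 + cid * 9973 + oi),
                       core_mask = sub_core, core2_mask = sub_core2),
        error = function(e) {
          warning(sprintf("frame %d colony %d object %d quarantined: %s",
                          frame_idx, cid, oi, conditionMessage(e)))
          NULL
        })
      if (is.null(res)) next
      for (part in res) {
        lab_sub[part] <- next_part
        next_part <- next_part + 1L
      }
    }
    if (max(lab_sub) == 0) next
    ms <- merge_small_fragments(lab_sub, A)
    lab_sub <- merge_subcell_detections(ms$labels, species, config$t_valley)
    ## recover the boundary ring: the halo shifts the threshold contour
    ## about one pixel into the cell, while true cell extents (like the
    ## reference masks) tile the cell-cell interfaces; grow each region by
    ## one pixel into unclaimed colony foreground, nearest cell wins
    grow_dom <- cmask_sub &
      (matrix(EBImage::dilate(EBImage::Image((lab_sub > 0) * 1),
                              disc_brush(1)) > 0.5,
              nrow(lab_sub), ncol(lab_sub)))
    pgv <- EBImage::propagate(
      EBImage::Image(matrix(0, nrow(lab_sub), ncol(lab_sub))),
      seeds = EBImage::Image(lab_sub),
      mask = EBImage::Image(grow_dom * 1) > 0.5)
    lab_sub <- matrix(as.integer(EBImage::imageData(pgv)),
                      nrow(lab_sub), ncol(lab_sub))

    for (k in sort(unique(lab_sub[lab_sub > 0]))) {
      pix <- which(lab_sub == k, arr.ind = TRUE)
      g <- cell_geometry(pix, cal)
      cr <- g$centroid_row + bb[1] - 1; cc <- g$centroid_col + bb[3] - 1
      fl_tot <- fl_mean <- NA_real_
      if (!is.null(fluor_frame)) {
        v <- fluor_frame[cbind(pix[, 1] + bb[1] - 1L, pix[, 2] + bb[3] - 1L)]
        fl_tot <- sum(v); fl_mean <- mean(v)
      }
      cells_list[[length(cells_list) + 1L]] <- data.frame(
        cell_instant_id = next_cell, frame = frame_idx, colony_id = cid,
        centroid_row = cr, centroid_col = cc,
        area_px = nrow(pix), area_um2 = nrow(pix) * cal^2,
        length_um = g$length_um, width_um = g$width_um,
        orientation = g$orientation,
        dist_to_colony_centroid_um =
          sqrt((cr - ccent[1])^2 + (cc - ccent[2])^2) * cal,
        fluor_total = fl_tot, fluor_mean = fl_mean,
        on_colony_boundary = any(boundary_band[pix]),
        undersized = nrow(pix) < A)
      out_label[cbind(pix[, 1] + bb[1] - 1L, pix[, 2] + bb[3] - 1L)] <- next_cell
      next_cell <- next_cell + 1L
    }
  }
  cells <- if (length(cells_list)) do.call(rbind, cells_list) else
    data.frame(cell_instant_id = integer(), frame = integer(),
               colony_id = integer(), centroid_row = numeric(),
               centroid_col = numeric(), area_px = integer(),
               area_um2 = numeric(), length_um = numeric(),
               width_um = numeric(), orientation = numeric(),
               dist_to_colony_centroid_um = numeric(),
               fluor_total = numeric(), fluor_mean = numeric(),
               on_colony_boundary = logical(), undersized = logical())
  list(cells = cells, label = out_label)
}

## Segment one cell object (crop-local). Returns a list of pixel index
## matrices (n x 2), one per cell candidate, in crop coordinates.
segment_object <- function(obj, species, config, prune, seed,
                           core_mask = NULL, core2_mask = NULL) {
  mask <- obj$mask
  bb <- grow_bbox(obj$bbox, 1, dim(mask))
  sub <- crop_bbox(mask, bb)
  to_full <- function(pix) cbind(pix[, 1] + bb[1] - 1L, pix[, 2] + bb[3] - 1L)

  if (sum(sub) < 4) return(list(to_full(which(sub, arr.ind = TRUE))))
  ## noise speckle inside cell bodies makes skeletons loop; fill it (real
  ## interface lines connect to the outside and are preserved)
  sub_f <- fill_small_holes(sub, max_area = ceiling(prune^2 / 2))
  cls <- classify_object(sub_f, prune_len = prune)
  if (cls$klass == "collinear") {
    cl <- order_centerline(cls$skeleton)
    curve <- if (is.null(cl)) NULL else distance_curve(sub_f, cl)
    if (is.null(curve)) return(list(to_full(which(sub, arr.ind = TRUE))))
    valleys <- find_deep_valleys(curve, config$t_valley)
    A <- min_fragment_area(species)
    parts <- suppressWarnings(split_collinear(sub, curve, valleys, A))
    return(lapply(parts, function(p) to_full(p$pixels)))
  }
  ## complex route: seed the watershed with conservative cores when the
  ## object holds several of them
  markers <- NULL
  if (!is.null(core_mask)) {
    core_sub <- fill_small_holes(crop_bbox(core_mask, bb) & sub,
                                 max_area = ceiling(prune^2 / 2))
    core2_sub <- if (!is.null(core2_mask)) crop_bbox(core2_mask, bb) & sub
                 else NULL
    if (any(core_sub)) {
      ml <- label_components(core_sub)
      ## ignore speck cores below a quarter of the minimum fragment area
      sz <- tabulate(ml[ml > 0])
      keep <- which(sz >= min_fragment_area(species) / 4)
      if (length(keep) >= 2 || (length(keep) >= 1 && !is.null(core2_sub))) {
        markers <- matrix(0L, nrow(ml), ncol(ml))
        nxt <- 1L
        for (k in keep) {
          selm <- ml == k
          subdivided <- FALSE
          if (!is.null(core2_sub)) {
            ## stiffer-threshold evidence: a core that splits at the
            ## second level is a fused pair; partition it by proximity
            m2 <- label_components(core2_sub & selm)
            sz2 <- tabulate(m2[m2 > 0])
            keep2 <- which(sz2 >= min_fragment_area(species) / 8)
            if (length(keep2) >= 2) {
              m2k <- matrix(match(m2, keep2, nomatch = 0L), nrow(m2), ncol(m2))
              pg <- EBImage::propagate(
                EBImage::distmap(EBImage::Image(selm * 1)),
                seeds = EBImage::Image(m2k),
                mask = EBImage::Image(selm * 1) > 0.5)
              pgm <- matrix(as.integer(EBImage::imageData(pg)),
                            nrow(ml), ncol(ml))
              for (j in seq_along(keep2)) {
                markers[pgm == j] <- nxt
                nxt <- nxt + 1L
              }
              subdivided <- TRUE
            }
          }
          if (!subdivided) { markers[selm] <- nxt; nxt <- nxt + 1L }
        }
        if (max(markers) < 2) markers <- NULL
      }
    }
  }
  ws <- watershed_candidates(sub, markers = markers)
  pz <- puzzle_solve(ws$labels, species, config$t_valley)
  pz$labels <- refine_fragments(pz$labels, species, config$t_valley)
  pz$centers <- fragment_centers(pz$labels)
  C <- nrow(pz$centers)
  if (C <= 1) return(list(to_full(which(sub, arr.ind = TRUE))))
  pixels <- which(sub, arr.ind = TRUE)
  ## distance weights: distance to the nearest cell-boundary evidence.
  ## When conservative cores exist, the internal interfaces between
  ## touching cells are boundaries too, so the transform runs on the core
  ## mask; point density then peaks along the cells' medial axes and stays
  ## low in the evidence-free interface zones.
  if (!is.null(markers)) {
    dtc <- matrix(as.numeric(EBImage::imageData(
      EBImage::distmap(EBImage::Image(core_sub * 1)))),
      nrow(sub), ncol(sub))
    d_all <- dtc[pixels]
    d_all[d_all <= 0] <- 0.25
  } else {
    dt <- matrix(as.numeric(EBImage::imageData(
      EBImage::distmap(EBImage::Image(sub * 1)))), nrow(sub), ncol(sub))
    d_all <- dt[pixels]
    d_all[d_all <= 0] <- min(d_all[d_all > 0])
  }
  set.seed(seed)
  ## divide and conquer within the object: the mixture is fitted per
  ## connected chunk of <= 10 touching fragments, so a drifting component
  ## can never slide across a large colony-wide slab
  chunks <- fragment_chunks(pz$labels, max_size = 10000)
  frag_at_all <- pz$labels[pixels]
  comp <- integer(nrow(pixels))
  comp_off <- 0L
  for (ch in chunks) {
    sel <- frag_at_all %in% ch
    if (!any(sel)) next
    pix_ch <- pixels[sel, , drop = FALSE]
    ctrs <- pz$centers[pz$centers$fragment %in% ch, , drop = FALSE]
    Cc <- nrow(ctrs)
    if (Cc <= 1) { comp[sel] <- comp_off + 1L; comp_off <- comp_off + 1L; next }
    N <- point_budget(Cc, species)
    cloud <- generate_points(pix_ch, d_all[sel], N,
                             sigma2 = config$point_sigma2, dim_img = dim(sub))
    centers <- as.matrix(ctrs[, c("centroid_row", "centroid_col")])
    init <- suppressWarnings(init_mixture(cloud, centers))
    fit <- fit_gmm_mml(cloud, init, cov_floor = config$point_sigma2)
    cc <- assign_pixels(pix_ch, cloud, fit)
    ## hard evidence wins: all core pixels of one fragment vote as a block
    if (!is.null(markers)) {
      frag_at <- frag_at_all[sel]
      in_core <- core_sub[pix_ch]
      for (fr in sort(unique(frag_at[frag_at > 0 & in_core]))) {
        ss <- frag_at == fr & in_core
        maj <- as.integer(names(which.max(table(cc[ss]))))
        cc[ss] <- maj
      }
    }
    comp[sel] <- comp_off + cc
    comp_off <- comp_off + fit$n_components
  }
  comp[comp == 0L] <- comp_off + 1L   # stray pixels outside any fragment
  ## split non-connected component regions into connected parts
  parts <- list()
  for (m in sort(unique(comp))) {
    mm <- matrix(FALSE, nrow(sub), ncol(sub))
    mm[pixels[comp == m, , drop = FALSE]] <- TRUE
    lab <- label_components(mm)
    for (k in seq_len(max(lab)))
      parts[[length(parts) + 1L]] <- to_full(which(lab == k, arr.ind = TRUE))
  }
  parts
}

## Geometry of one cell region: principal-axis length/width, orientation.
cell_geometry <- function(pix, cal) {
  ctr <- colMeans(pix)
  if (nrow(pix) == 1) {
    return(list(centroid_row = ctr[1], centroid_col = ctr[2],
                length_um = cal, width_um = cal, orientation = 0))
  }
  X <- sweep(pix, 2, ctr)
  S <- crossprod(X) / nrow(pix)
  eg <- eigen(S, symmetric = TRUE)
  v1 <- eg$vectors[, 1]; v2 <- eg$vectors[, 2]
  p1 <- X %*% v1; p2 <- X %*% v2
  len <- (max(p1) - min(p1) + 1) * cal
  wid <- (max(p2) - min(p2) + 1) * cal
  if (wid > len) { tmp <- len; len <- wid; wid <- tmp; v1 <- v2 }
  list(centroid_row = ctr[1], centroid_col = ctr[2],
       length_um = len, width_um = wid,
       orientation = atan2(v1[1], v1[2]))
}

#' Run preprocessing, colony analysis and segmentation over a frame stack
#'
#' @param stack a [load_frames()]-style stack (or a `sim_movie` converted
#'   with [stack_from_movie()]).
#' @param species a [species_config()].
#' @param config a [segmentation_config()].
#' @param frames optional subset of frame indices to segment (colony masks
#'   are still built for all requested frames).
#' @return list with `stack` (preprocessed), `colony` (tracking result of
#'   [track_colony_movie()], with `cell_count` filled), `segmentation`
#'   (per-frame [segment_frame()] results, named by frame index) and
#'   `cells` (combined cell-instant table with `colony_track_id`).
#' @export
segment_movie <- function(stack, species, config = segmentation_config(),
                          frames = NULL) {
  frames <- frames %||% seq_along(stack$frames)
  pp <- preprocess_stack(stack)
  wpx <- species$cell_width / species$cal_factor
  A <- min_fragment_area(species)
  labels <- lapply(frames, function(f) {
    corr <- correct_background(pp$frames[[f]], ball_radius_px = round(5 * wpx),
                               cells = if (species$modality == "fluorescence")
                                 "bright" else "dark")
    build_colony_mask(corr, close_radius_px = max(3, round(wpx)),
                      min_area_px = A)
  })
  colony <- track_colony_movie(labels, species$cal_factor)
  ## renumber colony table frames to the original movie frame indices
  colony$colonies$frame <- frames[colony$colonies$frame]
  colony$events$frame <- frames[colony$events$frame]
  seg <- vector("list", length(frames))
  names(seg) <- as.character(frames)
  all_cells <- list()
  for (i in seq_along(frames)) {
    f <- frames[i]
    fl <- if (!is.null(stack$fluorescence_frames))
      stack$fluorescence_frames[[f]] else NULL
    sf <- segment_frame(pp$frames[[f]], labels[[i]], species, config,
                        frame_idx = f, fluor_frame = fl)
    ## colony label id -> track id
    ctab <- colony$colonies[colony$colonies$frame == f, ]
    if (nrow(sf$cells) > 0) {
      sf$cells$colony_track_id <-
        ctab$track_id[match(sf$cells$colony_id, ctab$colony_id)]
    } else sf$cells$colony_track_id <- integer(0)
    seg[[i]] <- sf
    all_cells[[i]] <- sf$cells
  }
  cells <- do.call(rbind, all_cells)
  ## fill per-colony cell counts
  if (!is.null(cells) && nrow(cells) > 0) {
    cnt <- aggregate(cell_instant_id ~ frame + colony_track_id, data = cells,
                     FUN = length)
    names(cnt)[3] <- "n"
    key <- paste(colony$colonies$frame, colony$colonies$track_id)
    colony$colonies$cell_count <-
      cnt$n[match(key, paste(cnt$frame, cnt$colony_track_id))]
  }
  list(stack = pp, colony = colony, segmentation = seg, cells = cells)
}

#' Wrap a simulated movie as a frame stack
#'
#' @param movie a [simulate_movie()] result.
#' @return a `frame_stack` sharing the movie's frames and calibration.
#' @export
stack_from_movie <- function(movie) {
  structure(list(frames = movie$frames, cal_factor = movie$params$cal_factor,
                 sampling_period = movie$params$sampling_period,
                 modality = movie$params$modality,
                 fluorescence_frames = NULL),
            class = "frame_stack")
}
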