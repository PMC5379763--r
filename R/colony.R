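## Colony mask construction and colony tracking with merge detection.

#' Rolling-ball background estimation
#'
#' Morphological background estimate: grayscale closing with a disc
#' structuring element removes objects darker than the background (phase
#' contrast / bright field); opening is used instead when cells are brighter
#' than the background (fluorescence-like). The ball radius must exceed the
#' expected cell width in pixels so that cells are erased from the estimate
#' while large-scale illumination is kept.
#'
#' @param frame numeric intensity matrix.
#' @param ball_radius_px structuring-element radius in pixels.
#' @param cells `"dark"` or `"bright"` relative to the background.
#' @return background matrix, same shape.
#' @export
estimate_background <- function(frame, ball_radius_px, cells = c("dark", "bright")) {
  cells <- match.arg(cells)
  stopifnot(ball_radius_px >= 1)
  img <- EBImage::Image(frame)
  br <- disc_brush(ball_radius_px)
  bg <- if (cells == "dark") EBImage::closing(img, br) else EBImage::opening(img, br)
  matrix(as.numeric(EBImage::imageData(bg)), nrow(frame), ncol(frame))
}

#' Background-corrected frame
#'
#' Subtracts the rolling-ball background and re-centres on the background
#' median so flat regions stay flat and in range.
#' @inheritParams estimate_background
#' @return corrected matrix in \[0, 1\].
#' @export
correct_background <- function(frame, ball_radius_px, cells = c("dark", "bright")) {
  bg <- estimate_background(frame, ball_radius_px, cells)
  clamp(frame - bg + median(bg), 0, 1)
}

## -------------------------------------------------------------------------
## Canny edge detection (Sobel gradient, non-maximum suppression, hysteresis)

canny_edges <- function(frame, sigma = 1, low = NULL, high = NULL) {
  sm <- gauss_blur(frame, sigma)
  sx <- (mat_shift_replicate(sm, 0, -1) - mat_shift_replicate(sm, 0, 1)) / 2 # d/dcol
  sy <- (mat_shift_replicate(sm, -1, 0) - mat_shift_replicate(sm, 1, 0)) / 2 # d/drow
  mag <- sqrt(sx^2 + sy^2)
  if (is.null(high)) {                      # two-sigma heuristic
    mu <- mean(mag); s <- sd(mag)
    if (s < 1e-12) return(matrix(FALSE, nrow(frame), ncol(frame)))
    high <- mu + 2 * s
    low <- mu + s
  }
  if (is.null(low)) low <- high / 2
  ## quantize gradient direction into 4 bins and suppress non-maxima
  ang <- atan2(sy, sx)
  bin <- (round(ang / (pi / 4)) %% 4)       # 0:E, 1:NE, 2:N, 3:NW
  nmax <- matrix(FALSE, nrow(frame), ncol(frame))
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (b in 0:3) {
    o <- offs[[b + 1]]
    fwd <- mat_shift(mag, -o[1], -o[2], fill = 0)
    bwd <- mat_shift(mag, o[1], o[2], fill = 0)
    nmax <- nmax | (bin == b & mag >= fwd & mag >= bwd)
  }
  strong <- nmax & mag >= high
  weak <- nmax & mag >= low
  ## hysteresis: keep weak-edge components that contain a strong pixel
  lab <- label_components(weak)
  keep <- unique(lab[strong & lab > 0])
  lab > 0 & lab %in% keep
}

#' Build the global colony mask of a frame
#'
#' Union of the Otsu foreground (deviation from the background level, so both
#' dark cell bodies and bright halos count) and filled Canny edge contours,
#' followed by morphological closing and hole filling. Each connected
#' component of the result is one colony region; components smaller than
#' `min_area_px` are dropped as specks.
#'
#' @param corrected background-corrected intensity matrix in \[0, 1\].
#' @param close_radius_px radius of the closing element (about one cell
#'   width) bridging the gaps between touching cells.
#' @param min_area_px minimum colony component area (default: the expected
#'   single-cell pole area; see [min_fragment_area()]).
#' @return integer label matrix; 0 = background, k = colony k. An empty mask
#'   (no colonies) is a valid result.
#' @export
build_colony_mask <- function(corrected, close_radius_px = 5, min_area_px = 0) {
  if (diff(range(corrected)) < 1e-6)
    return(matrix(0L, nrow(corrected), ncol(corrected)))  # featureless frame
  dev <- abs(corrected - median(corrected))
  th <- EBImage::otsu(EBImage::Image(clamp(dev, 0, 1)))
  fg_otsu <- dev > th
  edges <- canny_edges(corrected)
  fg <- fg_otsu | edges
  img <- EBImage::Image(fg * 1)
  img <- EBImage::closing(img, disc_brush(close_radius_px))
  img <- EBImage::fillHull(img)
  ## generous rim: outermost cell pixels blur into the halo and must not
  ## be clipped off the colony
  img <- EBImage::dilate(img, disc_brush(2))
  mask <- matrix(as.numeric(EBImage::imageData(img)) > 0.5,
                 nrow(corrected), ncol(corrected))
  lab <- label_components(mask)
  if (min_area_px > 0 && max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    ## relabel compactly
    old <- sort(unique(lab[lab > 0]))
    lab <- matrix(match(lab, old, nomatch = 0L), nrow(lab), ncol(lab))
  }
  lab
}

#' Per-colony region properties for one frame
#'
#' @param colony_label integer label matrix from [build_colony_mask()].
#' @param cal_factor um/pixel.
#' @param frame 1-based frame index.
#' @return data.frame with colony_id, frame, area_px, area_um2, centroid and
#'   half-open bounding box columns.
#' @export
colony_props <- function(colony_label, cal_factor, frame = 1L) {
  ids <- sort(unique(colony_label[colony_label > 0]))
  if (length(ids) == 0)
    return(data.frame(colony_id = integer(), frame = integer(),
                      area_px = integer(), area_um2 = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      bb_r1 = integer(), bb_r2 = integer(),
                      bb_c1 = integer(), bb_c2 = integer()))
  out <- do.call(rbind, lapply(ids, function(id) {
    w <- which(colony_label == id, arr.ind = TRUE)
    data.frame(colony_id = id, frame = frame, area_px = nrow(w),
               area_um2 = nrow(w) * cal_factor^2,
               centroid_row = mean(w[, 1]), centroid_col = mean(w[, 2]),
               bb_r1 = min(w[, 1]), bb_r2 = max(w[, 1]) + 1L,
               bb_c1 = min(w[, 2]), bb_c2 = max(w[, 2]) + 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Match colonies between two consecutive frames
#'
#' A previous-frame colony matches the current-frame colony whose bounding
#' box contains its centroid. A current colony matched by no previous colony
#' is an `appear` event; two or more previous centroids inside one current
#' bounding box is a `merge`; a previous colony matching nothing is an
#' `exit`. When one previous centroid falls inside several current bounding
#' boxes, the current colony with maximal mask overlap wins (tie: smaller
#' colony id).
#'
#' @param prev,curr `colony_props()` data.frames of consecutive frames.
#' @param prev_label,curr_label their label matrices (used only for overlap
#'   disambiguation).
#' @return list with `matching` (data.frame prev_id, curr_id) and `events`
#'   (data.frame event, colony_id, partner_id).
#' @export
track_colonies <- function(prev, curr, prev_label = NULL, curr_label = NULL) {
  match_of <- rep(NA_integer_, nrow(prev))
  for (i in seq_len(nrow(prev))) {
    r <- prev$centroid_row[i]; cc <- prev$centroid_col[i]
    inside <- which(curr$bb_r1 <= r & r < curr$bb_r2 &
                    curr$bb_c1 <= cc & cc < curr$bb_c2)
    if (length(inside) == 1) {
      match_of[i] <- curr$colony_id[inside]
    } else if (length(inside) > 1) {
      ov <- vapply(inside, function(j) {
        if (is.null(prev_label) || is.null(curr_label)) return(0)
        sum(prev_label == prev$colony_id[i] & curr_label == curr$colony_id[j])
      }, numeric(1))
      best <- inside[ov == max(ov)]
      match_of[i] <- min(curr$colony_id[best])
    }
  }
  matching <- data.frame(prev_id = prev$colony_id, curr_id = match_of)
  events <- data.frame(event = character(), colony_id = integer(),
                       partner_id = integer())
  for (j in curr$colony_id) {
    srcs <- matching$prev_id[!is.na(matching$curr_id) & matching$curr_id == j]
    if (length(srcs) == 0)
      events <- rbind(events, data.frame(event = "appear", colony_id = j,
                                         partner_id = NA_integer_))
    if (length(srcs) >= 2)
      for (s in srcs[-which.min(srcs)])
        events <- rbind(events, data.frame(event = "merge", colony_id = s,
                                           partner_id = min(srcs)))
  }
  for (i in which(is.na(matching$curr_id)))
    events <- rbind(events, data.frame(event = "exit",
                                       colony_id = prev$colony_id[i],
                                       partner_id = NA_integer_))
  list(matching = matching, events = events)
}

#' Track colonies across a whole movie
#'
#' Applies [track_colonies()] frame by frame and assigns stable track ids.
#' On a merge the surviving track id is the lowest of the merging ids and
#' pre-merge history is retained; merged and exited tracks carry no frames
#' after their terminal event.
#'
#' @param labels list of per-frame colony label matrices.
#' @param cal_factor um/pixel.
#' @return list with `colonies` (per-frame colony table with `track_id`) and
#'   `events` (data.frame frame, event, track_id, partner_track_id).
#' @export
track_colony_movie <- function(labels, cal_factor) {
  props <- lapply(seq_along(labels), function(f)
    colony_props(labels[[f]], cal_factor, frame = f))
  n <- length(labels)
  events <- data.frame(frame = integer(), event = character(),
                       track_id = integer(), partner_track_id = integer())
  if (n == 0) return(list(colonies = do.call(rbind, props), events = events))
  track_of <- list()  # per frame: colony_id -> track_id
  next_track <- 1L
  p1 <- props[[1]]
  t1 <- setNames(seq_len(nrow(p1)), p1$colony_id)
  next_track <- nrow(p1) + 1L
  track_of[[1]] <- t1
  if (nrow(p1) > 0)
    events <- rbind(events, data.frame(frame = 1L, event = "appear",
                                       track_id = unname(t1),
                                       partner_track_id = NA_integer_))
  for (f in seq_len(n - 1)) {
    tr <- track_colonies(props[[f]], props[[f + 1]],
                         labels[[f]], labels[[f + 1]])
    cur_map <- integer(0)
    for (j in props[[f + 1]]$colony_id) {
      srcs <- tr$matching$prev_id[!is.na(tr$matching$curr_id) &
                                  tr$matching$curr_id == j]
      if (length(srcs) == 0) {
        cur_map[as.character(j)] <- next_track
        events <- rbind(events, data.frame(frame = f + 1L, event = "appear",
                                           track_id = next_track,
                                           partner_track_id = NA_integer_))
        next_track <- next_track + 1L
      } else {
        src_tracks <- unname(track_of[[f]][as.character(srcs)])
        surv <- min(src_tracks)
        cur_map[as.character(j)] <- surv
        if (length(src_tracks) > 1)
          for (s in setdiff(src_tracks, surv))
            events <- rbind(events, data.frame(frame = f + 1L, event = "merge",
                                               track_id = s,
                                               partner_track_id = surv))
      }
    }
    for (i in which(is.na(tr$matching$curr_id))) {
      events <- rbind(events,
                      data.frame(frame = f + 1L, event = "exit",
                                 track_id = unname(track_of[[f]][as.character(
                                   tr$matching$prev_id[i])]),
                                 partner_track_id = NA_integer_))
    }
    track_of[[f + 1]] <- cur_map
  }
  colonies <- do.call(rbind, lapply(seq_len(n), function(f) {
    p <- props[[f]]
    if (nrow(p) == 0) return(p)
    p$track_id <- unname(track_of[[f]][as.character(p$colony_id)])
    p
  }))
  list(colonies = colonies, events = events)
}

#' Colony growth curves
#'
#' Time series of area and cell count for one colony track. Cell counts are
#' available once segmentation has filled the `cell_count` column (otherwise
#' NA).
#'
#' @param colonies colony table from [track_colony_movie()] (optionally with
#'   a `cell_count` column).
#' @param track_id track to extract.
#' @param sampling_period minutes per frame.
#' @return data.frame frame, time_min, area_um2, cell_count.
#' @export
colony_growth_curves <- function(colonies, track_id, sampling_period = 1) {
  d <- colonies[colonies$track_id == track_id, , drop = FALSE]
  d <- d[order(d$frame), ]
  data.frame(frame = d$frame, time_min = (d$frame - 1) * sampling_period,
             area_um2 = d$area_um2,
             cell_count = if ("cell_count" %in% names(d)) d$cell_count
                          else NA_integer_)
}
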