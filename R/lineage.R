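## Frame-to-frame cell correspondence and lineage/divisions trees.
##
## The tracker is an overlap-maximization stand-in with a pluggable
## interface: consecutive frames are matched per colony by pixel overlap
## after translating the earlier frame by the colony centroid displacement;
## a cell whose area is covered >= 60% by two next-frame cells (each
## >= 20%) has divided.

#' Track cells across frames and build the lineage forest
#'
#' @param seg per-frame segmentation results: list of lists with `cells`
#'   and `label` (as returned in `segment_movie()$segmentation`).
#' @param frames frame indices corresponding to `seg` entries.
#' @param sampling_period minutes per frame.
#' @param div_combined,div_each overlap thresholds for calling a division.
#' @param tracker optional replacement function
#'   `function(prev_label, curr_label, shift)` returning the overlap matrix;
#'   the default counts overlapping pixels after integer translation.
#' @return object of class `lineage_forest`: `nodes` (cell table: cell_id,
#'   colony_track_id, parent_cell_id, birth_frame, division_frame, fate,
#'   generation), `instants` (frame, cell_instant_id, cell_id).
#' @export
track_cells <- function(seg, frames = as.integer(names(seg)),
                        sampling_period = 1,
                        div_combined = 0.6, div_each = 0.2,
                        tracker = NULL) {
  n <- length(seg)
  stopifnot(n >= 1)
  overlap_fun <- tracker %||% overlap_counts
  ## active cell id per detection of the current frame
  nodes <- list()
  instants <- list()
  next_id <- 1L
  f1 <- frames[1]
  cur_cells <- seg[[1]]$cells
  cur_map <- integer(nrow(cur_cells))  # detection row -> cell_id
  for (i in seq_len(nrow(cur_cells))) {
    cur_map[i] <- next_id
    nodes[[next_id]] <- list(cell_id = next_id,
                             colony_track_id = cur_cells$colony_track_id[i] %||% NA,
                             parent_cell_id = NA_integer_,
                             birth_frame = f1, division_frame = NA_integer_,
                             fate = "censored")
    next_id <- next_id + 1L
  }
  instants[[1]] <- data.frame(frame = f1,
                              cell_instant_id = cur_cells$cell_instant_id,
                              cell_id = cur_map)

  for (t in seq_len(n - 1)) {
    prev <- seg[[t]]; curr <- seg[[t + 1]]
    fprev <- frames[t]; fcurr <- frames[t + 1]
    prev_map <- cur_map
    ## colony displacement: mean centroid shift between matched colonies
    shift <- c(0, 0)
    if (nrow(prev$cells) > 0 && nrow(curr$cells) > 0) {
      shift <- round(c(
        mean(curr$cells$centroid_row) - mean(prev$cells$centroid_row),
        mean(curr$cells$centroid_col) - mean(prev$cells$centroid_col)))
    }
    O <- overlap_fun(prev$label, curr$label, shift)
    np <- nrow(prev$cells); nc <- nrow(curr$cells)
    cur_map <- integer(nc)
    if (np == 0 || nc == 0 || length(O) == 0) {
      parent_of <- rep(0L, nc)
    } else {
      parent_of <- apply(O, 2, function(col) if (max(col) > 0) which.max(col) else 0L)
    }
    for (i in seq_len(np)) {
      kids <- which(parent_of == i)
      if (length(kids) == 0) {
        nodes[[prev_map[i]]]$fate <- "lost"
        next
      }
      area_i <- prev$cells$area_px[i]
      if (length(kids) > 2) {   # ambiguous: keep the two largest overlaps
        kids <- kids[order(O[i, kids], decreasing = TRUE)]
        for (k in kids[-(1:2)]) parent_of[k] <- 0L
        kids <- kids[1:2]
      }
      if (length(kids) == 2) {
        ov <- O[i, kids]
        if (sum(ov) >= div_combined * area_i && all(ov >= div_each * area_i)) {
          ## division
          nodes[[prev_map[i]]]$fate <- "divided"
          nodes[[prev_map[i]]]$division_frame <- fcurr
          for (k in kids) {
            cur_map[k] <- next_id
            nodes[[next_id]] <- list(cell_id = next_id,
                                     colony_track_id = curr$cells$colony_track_id[k] %||% NA,
                                     parent_cell_id = prev_map[i],
                                     birth_frame = fcurr,
                                     division_frame = NA_integer_,
                                     fate = "censored")
            next_id <- next_id + 1L
          }
          next
        }
        ## not a division: larger overlap continues, other detaches
        k2 <- kids[which.min(ov)]
        parent_of[k2] <- 0L
        kids <- kids[which.max(ov)]
      }
      cur_map[kids[1]] <- prev_map[i]   # continuation
    }
    ## unmatched current detections start new trees
    for (k in which(cur_map == 0L)) {
      cur_map[k] <- next_id
      nodes[[next_id]] <- list(cell_id = next_id,
                               colony_track_id = curr$cells$colony_track_id[k] %||% NA,
                               parent_cell_id = NA_integer_,
                               birth_frame = fcurr, division_frame = NA_integer_,
                               fate = "censored")
      next_id <- next_id + 1L
    }
    instants[[t + 1]] <- data.frame(frame = fcurr,
                                    cell_instant_id = curr$cells$cell_instant_id,
                                    cell_id = cur_map)
  }
  nodes_df <- do.call(rbind, lapply(nodes, function(x)
    data.frame(cell_id = x$cell_id, colony_track_id = x$colony_track_id,
               parent_cell_id = x$parent_cell_id, birth_frame = x$birth_frame,
               division_frame = x$division_frame, fate = x$fate)))
  ## generation = tree depth
  gen <- integer(nrow(nodes_df))
  ord <- order(nodes_df$birth_frame)
  for (i in ord) {
    p <- nodes_df$parent_cell_id[i]
    gen[i] <- if (is.na(p)) 0L else gen[nodes_df$cell_id == p] + 1L
  }
  nodes_df$generation <- gen
  structure(list(nodes = nodes_df, instants = do.call(rbind, instants),
                 sampling_period = sampling_period),
            class = "lineage_forest")
}

## pixel overlap counts between prev (translated by shift) and curr labels
overlap_counts <- function(prev_label, curr_label, shift = c(0, 0)) {
  pl <- mat_shift(prev_label, shift[1], shift[2], fill = 0L)
  sel <- pl > 0 & curr_label > 0
  np <- max(prev_label); nc <- max(curr_label)
  O <- matrix(0, np, nc)
  if (any(sel)) {
    tb <- table(pl[sel], curr_label[sel])
    O[cbind(as.integer(rownames(tb))[row(tb)],
            as.integer(colnames(tb))[col(tb)])] <- as.numeric(tb)
  }
  O
}

#' Condense a lineage forest into divisions trees
#'
#' Every cell's life span is contracted to a single node; edges run from a
#' dividing cell to its daughters. Non-root nodes therefore all correspond
#' to division events (leaf daughters carry their censored life).
#'
#' @param forest a [track_cells()] result.
#' @param attributes optional per-cell data.frame keyed by `cell_id` whose
#'   columns are attached to nodes (for coloring in external viewers).
#' @return igraph forest; vertex attributes include `fate`, `generation`,
#'   `is_division_node`.
#' @export
build_divisions_tree <- function(forest, attributes = NULL) {
  nd <- forest$nodes
  edges <- nd[!is.na(nd$parent_cell_id), c("parent_cell_id", "cell_id")]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$parent_cell_id),
                   to = as.character(edges$cell_id)),
    directed = TRUE,
    vertices = data.frame(name = as.character(nd$cell_id),
                          fate = nd$fate, generation = nd$generation,
                          birth_frame = nd$birth_frame,
                          is_division_node = nd$fate == "divided"))
  if (!is.null(attributes)) {
    idx <- match(as.integer(igraph::V(g)$name), attributes$cell_id)
    for (cl in setdiff(names(attributes), "cell_id"))
      g <- igraph::set_vertex_attr(g, cl, value = attributes[[cl]][idx])
  }
  g
}

#' Export lineage trees for external viewers
#'
#' Writes GraphML (node attributes preserved) plus a flat parent-child CSV.
#'
#' @param forest a [track_cells()] result.
#' @param path output path without extension.
#' @param attributes optional per-cell attribute table (see
#'   [build_divisions_tree()]).
#' @return invisible vector of the files written.
#' @export
export_trees <- function(forest, path, attributes = NULL) {
  g <- build_divisions_tree(forest, attributes)
  fg <- paste0(path, ".graphml")
  igraph::write_graph(g, fg, format = "graphml")
  fc <- paste0(path, "_cells.csv")
  write.csv(forest$nodes, fc, row.names = FALSE)
  invisible(c(fg, fc))
}
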