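## helper: fabricate segmentation-like input from ground-truth masks, so the
## tracker is tested in isolation from the segmenter
seg_from_truth <- function(movie, frames = seq_along(movie$label_masks)) {
  out <- lapply(frames, function(f) {
    lab <- movie$label_masks[[f]]
    ids <- sort(unique(lab[lab > 0]))
    rel <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
    cells <- do.call(rbind, lapply(seq_along(ids), function(i) {
      w <- which(rel == i, arr.ind = TRUE)
      data.frame(cell_instant_id = i, frame = f, colony_track_id = 1L,
                 centroid_row = mean(w[, 1]), centroid_col = mean(w[, 2]),
                 area_px = nrow(w),
                 length_um = NA_real_)
    }))
    list(cells = cells, label = rel, truth_ids = ids)
  })
  names(out) <- as.character(frames)
  out
}

test_that("a static single cell yields one node and no divisions", {
  lab <- matrix(0L, 30, 30); lab[10:20, 12:18] <- 1L
  cells <- data.frame(cell_instant_id = 1L, frame = 1L, colony_track_id = 1L,
                      centroid_row = 15, centroid_col = 15, area_px = sum(lab > 0),
                      length_um = 2)
  seg <- list(`1` = list(cells = cells, label = lab),
              `2` = list(cells = transform(cells, frame = 2L), label = lab))
  fr <- track_cells(seg, frames = 1:2, sampling_period = 5)
  expect_equal(nrow(fr$nodes), 1)
  expect_equal(fr$nodes$fate, "censored")
  expect_equal(nrow(fr$instants), 2)
})

test_that("ground-truth division pairs are recovered on noise-free masks", {
  m <- fix_clean_movie()
  seg <- seg_from_truth(m)
  fr <- track_cells(seg, frames = seq_along(m$frames),
                    sampling_period = m$params$sampling_period)
  ## map tracked division events back to truth ids via instants
  truth_divs <- m$lineage_truth
  got <- 0
  for (i in seq_len(nrow(truth_divs))) {
    f <- truth_divs$division_frame[i]
    if (f > length(m$frames)) next
    ## the truth parent's detection in frame f-1
    prev_ids <- seg[[f - 1]]$truth_ids
    det_parent <- match(truth_divs$parent_id[i], prev_ids)
    node_parent <- fr$instants$cell_id[fr$instants$frame == f - 1][det_parent]
    nd <- fr$nodes[fr$nodes$cell_id == node_parent, ]
    if (identical(nd$fate, "divided") && identical(nd$division_frame, f))
      got <- got + 1
  }
  ## count unique truth divisions inside the movie window
  n_divs <- length(unique(
    truth_divs$parent_id[truth_divs$division_frame <= length(m$frames)]))
  expect_gte(got / n_divs, 0.95)
})

test_that("generation equals tree depth and instants partition cleanly", {
  m <- fix_clean_movie()
  seg <- seg_from_truth(m)
  fr <- track_cells(seg, frames = seq_along(m$frames),
                    sampling_period = m$params$sampling_period)
  nd <- fr$nodes
  depth_of <- function(id) {
    d <- 0
    while (!is.na(nd$parent_cell_id[nd$cell_id == id])) {
      id <- nd$parent_cell_id[nd$cell_id == id]; d <- d + 1
    }
    d
  }
  expect_equal(nd$generation, as.integer(vapply(nd$cell_id, depth_of, numeric(1))),
               ignore_attr = TRUE)
  ## every instant belongs to exactly one node
  expect_false(any(duplicated(fr$instants[, c("frame", "cell_instant_id")])))
  ## children are born at the parent division frame
  kids <- nd[!is.na(nd$parent_cell_id), ]
  par <- nd[match(kids$parent_cell_id, nd$cell_id), ]
  expect_equal(kids$birth_frame, par$division_frame, ignore_attr = TRUE)
  ## divided cells have exactly two children
  tab <- table(kids$parent_cell_id)
  expect_true(all(tab == 2))
  expect_setequal(names(tab), as.character(nd$cell_id[nd$fate == "divided"]))
})

test_that("divisions tree is the condensation of the lineage", {
  m <- fix_clean_movie()
  seg <- seg_from_truth(m)
  fr <- track_cells(seg, frames = seq_along(m$frames),
                    sampling_period = m$params$sampling_period)
  g <- build_divisions_tree(fr)
  expect_equal(sum(igraph::V(g)$is_division_node),
               sum(fr$nodes$fate == "divided"))
  ## single-division toy forest: root + 2 leaves
  nodes <- data.frame(cell_id = 1:3, colony_track_id = 1,
                      parent_cell_id = c(NA, 1, 1), birth_frame = c(1, 4, 4),
                      division_frame = c(4, NA, NA),
                      fate = c("divided", "censored", "censored"),
                      generation = c(0, 1, 1))
  toy <- structure(list(nodes = nodes,
                        instants = data.frame(frame = 1, cell_instant_id = 1,
                                              cell_id = 1),
                        sampling_period = 5), class = "lineage_forest")
  gt <- build_divisions_tree(toy)
  expect_equal(igraph::vcount(gt), 3)
  expect_equal(igraph::ecount(gt), 2)
})

test_that("trees export to GraphML and CSV", {
  nodes <- data.frame(cell_id = 1:3, colony_track_id = 1,
                      parent_cell_id = c(NA, 1, 1), birth_frame = c(1, 4, 4),
                      division_frame = c(4, NA, NA),
                      fate = c("divided", "censored", "censored"),
                      generation = c(0, 1, 1))
  toy <- structure(list(nodes = nodes,
                        instants = data.frame(frame = 1, cell_instant_id = 1,
                                              cell_id = 1),
                        sampling_period = 5), class = "lineage_forest")
  d <- withr::local_tempdir()
  files <- export_trees(toy, file.path(d, "colony1"))
  expect_true(all(file.exists(files)))
  g2 <- igraph::read_graph(files[1], format = "graphml")
  expect_equal(igraph::vcount(g2), 3)
})
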