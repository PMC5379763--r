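test_that("watershed yields one fragment for a convex rod, more for crossings", {
  rod <- rod_mask(40, 80, 60, 9)
  ws <- watershed_candidates(rod)
  expect_equal(nrow(ws$centers), 1)

  ## two overlapping offset rods: two distance ridges, two basins
  two <- matrix(FALSE, 48, 81)
  two[15:23, 5:45] <- TRUE
  two[25:33, 35:75] <- TRUE
  wsx <- watershed_candidates(two)
  expect_gte(nrow(wsx$centers), 2)
  ## both true rod centres lie inside some fragment
  expect_true(wsx$labels[19, 25] > 0 && wsx$labels[29, 55] > 0)
  expect_false(wsx$labels[19, 25] == wsx$labels[29, 55])
})

test_that("solidity matches exact hull arithmetic", {
  rect <- which(matrix(TRUE, 10, 3), arr.ind = TRUE)
  expect_equal(solidity(rect), 1.0)
  ## L-shape: compare against a Monte-Carlo point-in-hull oracle
  L <- matrix(FALSE, 12, 12)
  L[1:10, 1:3] <- TRUE; L[8:10, 1:10] <- TRUE
  px <- which(L, arr.ind = TRUE)
  corners <- cbind(c(px[, 1] - 0.5, px[, 1] - 0.5, px[, 1] + 0.5, px[, 1] + 0.5),
                   c(px[, 2] - 0.5, px[, 2] + 0.5, px[, 2] - 0.5, px[, 2] + 0.5))
  hull_idx <- chull(corners[, 2], corners[, 1])
  V <- corners[hull_idx, , drop = FALSE]   # ordered hull vertices
  set.seed(8)
  trial <- cbind(runif(40000, 0.5, 12.5), runif(40000, 0.5, 12.5))
  nv <- nrow(V)
  pos <- neg <- rep(TRUE, nrow(trial))     # accept either vertex orientation
  for (j in seq_len(nv)) {
    a <- V[j, ]; b <- V[j %% nv + 1, ]
    cr <- (b[1] - a[1]) * (trial[, 2] - a[2]) -
          (b[2] - a[2]) * (trial[, 1] - a[1])
    pos <- pos & cr >= 0
    neg <- neg & cr <= 0
  }
  hull_mc <- max(mean(pos), mean(neg)) * 12 * 12
  expect_equal(solidity(px), nrow(px) / hull_mc, tolerance = 0.03)
  rod <- rod_mask(40, 80, 60, 9)
  expect_gte(solidity(which(rod, arr.ind = TRUE)), 0.95)
})

test_that("puzzle solving rejoins split rods but respects septa", {
  ## halves of one straight rod, artificially split mid-length
  rod <- rod_mask(40, 80, 60, 9)
  lab <- matrix(0L, 40, 80)
  lab[rod & col(rod) <= 40] <- 1L
  lab[rod & col(rod) > 40] <- 2L
  sp <- species_config(3.5, 1.1, 0.125)  # cell width 8.8 px
  out <- puzzle_solve(lab, sp, 0.70)
  expect_equal(nrow(out$centers), 1)

  ## two rods separated by a deep septum must stay apart
  bt <- bowtie_mask(40, 110, 45, 11, depth = 0.55)
  labb <- matrix(0L, 40, 110)
  labb[bt & col(bt) <= 55] <- 1L
  labb[bt & col(bt) > 55] <- 2L
  sp2 <- species_config(3.5, 1.375, 0.125)  # width 11 px
  out2 <- puzzle_solve(labb, sp2, 0.70)
  expect_equal(nrow(out2$centers), 2)

  ## side-by-side parallel rods must not merge either
  par2 <- matrix(0L, 40, 80)
  par2[rod_mask(40, 80, 60, 9, cr = 15)] <- 1L
  par2[rod_mask(40, 80, 60, 9, cr = 25)] <- 2L
  out3 <- puzzle_solve(par2, sp, 0.70)
  expect_equal(nrow(out3$centers), 2)
})

test_that("puzzle solving prefers the max-solidity merge", {
  ## T-shape: stem touching a bar; merging stem+bar is less solid than
  ## merging two collinear bar halves
  lab <- matrix(0L, 60, 60)
  lab[28:36, 5:30] <- 1L      # left half of horizontal bar
  lab[28:36, 31:55] <- 2L     # right half
  sp <- species_config(3.5, 1.1, 0.125)
  out <- puzzle_solve(lab, sp, 0.70)
  expect_equal(nrow(out$centers), 1)  # halves of a straight bar merge
})

test_that("point budget and minimum area match hand arithmetic", {
  sp <- species_config(3.5, 1.1, 0.125)
  expect_equal(point_budget(75, sp), 9240L)
  expect_equal(point_budget(6, sp), 740L)
  expect_error(point_budget(0, sp))
  expect_equal(min_fragment_area(sp), 0.25 * pi * 8.8^2, tolerance = 1e-12)
  expect_equal(min_fragment_area(species_config(2, 1, 1)), pi / 4)
  ## scaling law: doubling cal_factor quarters A
  a1 <- min_fragment_area(species_config(3.5, 1.1, 0.1))
  a2 <- min_fragment_area(species_config(3.5, 1.1, 0.2))
  expect_equal(a1 / a2, 4)
  ## random-parameter agreement with direct arithmetic
  set.seed(10)
  for (i in 1:20) {
    w <- runif(1, 0.5, 2); l <- w + runif(1, 0, 4); cf <- runif(1, 0.05, 0.5)
    ssp <- species_config(l, w, cf)
    Cc <- sample(1:80, 1)
    expect_equal(point_budget(Cc, ssp), as.integer(ceiling(0.5 * Cc * l * w / cf^2)))
    expect_equal(min_fragment_area(ssp), pi / 4 * (w / cf)^2)
  }
})

test_that("undersized fragments merge into their best-solidity neighbour", {
  sp <- species_config(3.5, 1.1, 0.125)
  A <- min_fragment_area(sp)   # ~60.8 px
  rod <- rod_mask(40, 80, 60, 9)
  lab <- matrix(0L, 40, 80)
  lab[rod] <- 1L
  lab[rod & col(rod) <= 16] <- 2L   # pole cap fragment (~30 px)
  expect_lt(sum(lab == 2), A)
  out <- merge_small_fragments(lab, A)
  expect_equal(max(out$labels), 1)
  ## isolated speck is retained but flagged undersized
  lab2 <- matrix(0L, 40, 80)
  lab2[rod] <- 1L
  lab2[5:9, 70:75] <- 2L
  out2 <- merge_small_fragments(lab2, A)
  expect_equal(max(out2$labels), 2)
  expect_length(out2$undersized, 1)
})
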