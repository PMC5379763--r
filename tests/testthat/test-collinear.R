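test_that("width curve of a rectangle rod is flat; a circle has no deep valley", {
  rect <- matrix(FALSE, 30, 70); rect[11:19, 6:65] <- TRUE
  cv <- distance_curve(rect)
  mid <- cv$widths[10:(length(cv$widths) - 10)]
  expect_lt(diff(range(mid)), 2)           # +-1 px discretization
  expect_equal(length(find_deep_valleys(cv, 0.7)), 0)

  circ <- matrix(FALSE, 41, 41)
  for (r in 1:41) for (c in 1:41)
    circ[r, c] <- (r - 21)^2 + (c - 21)^2 <= 15^2
  cls <- classify_object(circ, prune_len = 6)
  cl <- bactrace:::order_centerline(cls$skeleton)
  if (!is.null(cl) && nrow(cl) >= 5) {
    cvc <- distance_curve(circ, cl)
    expect_equal(length(find_deep_valleys(cvc, 0.7)), 0)
  } else succeed("circle skeleton degenerates to a point: no curve, no split")
})

test_that("a 0.7-width septum produces one valley at the septum position", {
  bt <- bowtie_mask(40, 110, 45, 11, depth = 0.65)
  cv <- distance_curve(bt)
  v <- find_deep_valleys(cv, 0.70)
  expect_equal(length(v), 1)
  expect_lt(abs(cv$centerline[v, 2] - 55), 3)  # septum at mid-column
})

test_that("deep-valley ratio arithmetic matches the stated examples", {
  expect_equal(find_deep_valleys(c(8, 9, 6, 9, 8), 0.70), 3L)
  expect_equal(length(find_deep_valleys(c(8, 9, 7, 9, 8), 0.70)), 0)
  expect_equal(length(find_deep_valleys(rep(5, 20), 0.7)), 0)
})

test_that("deep valleys agree with a brute-force extrema oracle", {
  ## independent oracle: exhaustive scan over all indices. Minima are
  ## interior; maxima may sit on the curve boundary (missing side counts
  ## as lower).
  oracle <- function(w, tv) {
    n <- length(w)
    is_min <- is_max <- rep(FALSE, n)
    for (i in 1:n) {
      ## nearest unequal neighbours (plateau-aware)
      l <- i - 1; while (l >= 1 && w[l] == w[i]) l <- l - 1
      r <- i + 1; while (r <= n && w[r] == w[i]) r <- r + 1
      if (l >= 1 && r <= n && w[l] > w[i] && w[r] > w[i]) is_min[i] <- TRUE
      if ((l < 1 || w[l] < w[i]) && (r > n || w[r] < w[i])) is_max[i] <- TRUE
    }
    ## plateau centres only
    res <- integer(0)
    for (i in which(is_min)) {
      run <- which(w == w[i] & seq_along(w) >= i)
      run <- run[cumsum(c(1, diff(run)) != 1) == 0]
      centre <- floor((i + max(run)) / 2)
      if (centre != i && w[centre] == w[i]) next  # count once per plateau
      lm <- which(is_max & seq_along(w) < i)
      rm <- which(is_max & seq_along(w) > i)
      if (!length(lm) || !length(rm)) next
      if (w[i] / w[max(lm)] <= tv && w[i] / w[min(rm)] <= tv)
        res <- c(res, centre)
    }
    unique(as.integer(res))
  }
  set.seed(99)
  for (rep in 1:200) {
    w <- 8 * exp(cumsum(rnorm(sample(10:40, 1), 0, 0.25)))
    tv <- runif(1, 0.6, 0.8)
    expect_identical(find_deep_valleys(w, tv), oracle(w, tv))
  }
})

test_that("splitting partitions the object and respects the minimum area", {
  bt <- bowtie_mask(40, 110, 45, 11, depth = 0.6)
  cv <- distance_curve(bt)
  v <- find_deep_valleys(cv, 0.70)
  parts <- split_collinear(bt, cv, v)
  expect_equal(length(parts), length(v) + 1)
  expect_equal(sum(vapply(parts, function(p) nrow(p$pixels), numeric(1))),
               sum(bt))
  ## no valleys: identity
  p0 <- split_collinear(bt, cv, integer(0))
  expect_length(p0, 1)
  expect_equal(nrow(p0[[1]]$pixels), sum(bt))
  ## a cut that would create a tiny sliver is refused
  vbad <- c(v, 3L)
  expect_warning(p2 <- split_collinear(bt, cv, vbad, min_area_px = 150))
  expect_equal(length(p2), 2)
})

test_that("pre-division pairs in fixtures split near truth centroids", {
  m <- fix_clean_movie()
  lt <- m$lineage_truth
  f <- lt$division_frame[1]
  kid_ids <- lt$child_id[lt$division_frame == f][1:2]
  lab <- m$label_masks[[f]]
  ## merge the two daughters into one object: emulates the pre-split blob
  blob <- lab %in% kid_ids
  dim(blob) <- dim(lab)
  obj <- list(mask = blob, pixels = which(blob, arr.ind = TRUE),
              bbox = bactrace:::mask_bbox(blob))
  parts <- bactrace:::segment_object(obj, default_species(),
                                     segmentation_config(rng_seed = 2),
                                     prune = 9, seed = 2)
  expect_equal(length(parts), 2)
  truth_cent <- lapply(kid_ids, function(id)
    colMeans(which(lab == id, arr.ind = TRUE)))
  got_cent <- lapply(parts, colMeans)
  d <- sapply(truth_cent, function(tc)
    min(sapply(got_cent, function(gc) sqrt(sum((tc - gc)^2)))))
  expect_lt(max(d), 3)
})
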