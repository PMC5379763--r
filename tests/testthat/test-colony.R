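test_that("rolling-ball background reproduces smooth illumination fields", {
  con <- matrix(0.6, 60, 60)
  expect_equal(estimate_background(con, 10), con)
  grad <- matrix(rep(seq(0.3, 0.5, length.out = 80), each = 60), 60, 80)
  bg <- estimate_background(grad, 15)
  inner <- 20:40
  expect_lt(max(abs(bg[inner, 20:60] - grad[inner, 20:60])), 0.02)
  ## a small dark cell is erased from the background estimate
  with_cell <- grad; with_cell[28:32, 38:44] <- 0.1
  bg2 <- estimate_background(with_cell, 15)
  expect_lt(max(abs(bg2[28:32, 38:44] - grad[28:32, 38:44])), 0.03)
})

test_that("colony mask finds blank frames, single and triple colonies", {
  expect_equal(max(build_colony_mask(matrix(0.5, 80, 80))), 0)

  m <- fix_noisy_movie()
  f <- length(m$frames)
  pp <- preprocess_stack(stack_from_movie(m))
  corr <- correct_background(pp$frames[[f]], 44)
  lab <- build_colony_mask(corr, close_radius_px = 9, min_area_px = 60)
  expect_equal(max(lab), 1)
  ## Jaccard vs true foreground dilated by the PSF radius
  truth <- m$label_masks[[f]] > 0
  tr_d <- EBImage::dilate(EBImage::Image(truth * 1),
                          EBImage::makeBrush(5, "disc")) > 0.5
  jac <- sum(lab > 0 & tr_d) / sum(lab > 0 | tr_d)
  expect_gte(jac, 0.9)
  expect_gte(sum(lab > 0 & truth) / sum(truth), 0.99)

  m3 <- fix_three_colony_movie()
  f3 <- length(m3$frames)
  pp3 <- preprocess_stack(stack_from_movie(m3))
  corr3 <- correct_background(pp3$frames[[f3]], 44)
  lab3 <- build_colony_mask(corr3, close_radius_px = 9, min_area_px = 60)
  expect_equal(max(lab3), 3)
})

test_that("colony tracking matches identity, merges and appearances", {
  lab1 <- matrix(0L, 60, 90)
  lab1[10:25, 10:30] <- 1L; lab1[35:50, 55:80] <- 2L
  p1 <- colony_props(lab1, 0.125, frame = 1)
  tr <- track_colonies(p1, p1, lab1, lab1)
  expect_equal(tr$matching$curr_id, tr$matching$prev_id)
  expect_equal(nrow(tr$events), 0)

  ## two colonies fuse into one component
  lab2 <- matrix(0L, 60, 90)
  lab2[10:50, 10:80] <- 1L
  p2 <- colony_props(lab2, 0.125, frame = 2)
  tr2 <- track_colonies(p1, p2, lab1, lab2)
  expect_true("merge" %in% tr2$events$event)
  ## a colony appearing from nothing
  lab3 <- lab1; lab3[5:12, 70:85] <- 3L
  p3 <- colony_props(lab3, 0.125, frame = 2)
  tr3 <- track_colonies(p1, p3, lab1, lab3)
  expect_true(any(tr3$events$event == "appear" & tr3$events$colony_id == 3))
})

test_that("track ids survive a merge with lowest-id convention", {
  lab1 <- matrix(0L, 60, 90)
  lab1[10:25, 10:30] <- 1L; lab1[35:50, 55:80] <- 2L
  lab2 <- matrix(0L, 60, 90); lab2[10:50, 10:80] <- 1L
  out <- track_colony_movie(list(lab1, lab1, lab2), 0.125)
  ev <- out$events
  expect_true(any(ev$event == "merge" & ev$frame == 3))
  surv <- out$colonies$track_id[out$colonies$frame == 3]
  expect_equal(surv, 1L)
  ## no rows for the merged-away track after the merge
  expect_false(any(out$colonies$track_id == 2 & out$colonies$frame >= 3))
})

test_that("colony growth curves are exponential on clean fixtures", {
  m <- fix_clean_movie()
  labs <- lapply(m$label_masks, function(l) (l > 0) * 1L)
  out <- track_colony_movie(labs, m$params$cal_factor)
  cc <- vapply(seq_along(m$frames), function(f)
    length(unique(m$label_masks[[f]][m$label_masks[[f]] > 0])), integer(1))
  out$colonies$cell_count <- cc[out$colonies$frame]
  gc <- colony_growth_curves(out$colonies, 1, m$params$sampling_period)
  expect_equal(nrow(gc), length(m$frames))
  fit <- lm(log(gc$cell_count) ~ gc$time_min)
  expect_gte(summary(fit)$r.squared, 0.9)
  expect_true(all(diff(gc$frame) == 1))
})
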