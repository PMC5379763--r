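test_that("a single static cell rasterizes to one clean label region", {
  p <- sim_params(seed = 1, n_founders = 1, n_frames = 1,
                  field_px = c(100, 100), noise_sigma = 0, psf_sigma = 0,
                  illumination_gradient = 0)
  m <- simulate_movie(p)
  lab <- m$label_masks[[1]]
  expect_identical(sort(unique(lab[lab > 0])), 1L)
  ## area equals the discretized spherocylinder footprint of the founder
  cell <- m$cells[1, ]
  len <- cell$l0  # frame 1 is t = 0
  ax <- bactrace:::cell_axis(c(cell$cx, cell$cy), cell$phi, len, cell$width)
  cal <- p$cal_factor
  gx <- rep((seq_len(100) - 0.5) * cal, each = 100)
  gy <- rep((seq_len(100) - 0.5) * cal, times = 100)
  pr <- bactrace:::point_segment_distance(gx, gy, ax$p1, ax$p2)
  expect_equal(sum(lab > 0), sum(pr$dist <= cell$width / 2))
})

test_that("simulation is bit-identical under identical parameters", {
  p <- sim_params(seed = 9, n_founders = 2, n_frames = 6,
                  field_px = c(200, 200), k_cv = 0, division_jitter = 0)
  m1 <- simulate_movie(p)
  m2 <- simulate_movie(p)
  expect_identical(m1$frames, m2$frames)
  expect_identical(m1$label_masks, m2$label_masks)
  expect_identical(m1$lineage_truth, m2$lineage_truth)
})

test_that("population growth rate matches the sampled elongation regime", {
  ## doubling time 25 min => count curve ~ exp(log(2)/25 * t)
  m <- fixture("growth_movie", function()
    simulate_movie(sim_params(seed = 7, n_founders = 1, n_frames = 26,
                              field_px = c(420, 420), noise_sigma = 0,
                              psf_sigma = 0)))
  counts <- vapply(seq_along(m$frames), function(f)
    sum(m$colony_truth$frame == f), numeric(1))
  t <- (seq_along(counts) - 1) * m$params$sampling_period
  sel <- counts >= 2           # skip the single-cell lag at the start
  fitk <- coef(lm(log(counts[sel]) ~ t[sel]))[2]
  expect_lt(abs(fitk - log(2) / 25) / (log(2) / 25), 0.25)
})

test_that("ground-truth counts equal brute-force unique-label counts", {
  m <- fix_three_colony_movie()
  f <- length(m$frames)
  gt <- ground_truth_counts(m, f)
  lab <- m$label_masks[[f]]
  ids <- unique(lab[lab > 0])
  ct <- m$colony_truth[m$colony_truth$frame == f, ]
  brute <- table(ct$colony_id[match(ids, ct$cell_id)])
  expect_equal(sum(gt$cell_count), length(ids))
  expect_equal(gt$cell_count, as.integer(brute[as.character(gt$colony_id)]),
               ignore_attr = TRUE)
  expect_error(ground_truth_counts(m, length(m$frames) + 1))
})

test_that("divisions in lineage_truth appear as label turnover in masks", {
  m <- fix_clean_movie()
  lt <- m$lineage_truth
  expect_gt(nrow(lt), 0)
  for (i in seq_len(nrow(lt))) {
    f <- lt$division_frame[i]
    if (f <= 1 || f > length(m$frames)) next
    prev_ids <- unique(m$label_masks[[f - 1]][m$label_masks[[f - 1]] > 0])
    curr_ids <- unique(m$label_masks[[f]][m$label_masks[[f]] > 0])
    expect_true(lt$parent_id[i] %in% prev_ids)
    expect_false(lt$parent_id[i] %in% curr_ids)
    expect_true(lt$child_id[i] %in% curr_ids)
  }
})

test_that("foreground area is non-decreasing in noise-free movies", {
  m <- fix_clean_movie()
  areas <- vapply(m$label_masks, function(l) sum(l > 0), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("sampled division lengths follow the configured gamma law", {
  ## pool the sampled division-length draws of all cells ever created
  ## (realized lengths at division are inspection-biased: small-threshold
  ## cells complete their lives sooner inside a finite movie)
  dls <- fixture("division_lengths", function() {
    out <- numeric(0)
    for (s in 1:4) {
      mm <- simulate_movie(sim_params(seed = 100 + s, n_founders = 3,
                                      n_frames = 30, field_px = c(460, 460),
                                      noise_sigma = 0, psf_sigma = 0))
      out <- c(out, mm$divided$sampled_division_length, mm$cells$div_len)
      if (length(out) >= 500) break
    }
    out
  })
  expect_gte(length(dls), 500)
  se <- sd(dls) / sqrt(length(dls))
  expect_lt(abs(mean(dls) - 5.0), 3 * se + 0.05)
  ## realized lengths at division sit at or above the sampled thresholds
  mm <- fix_clean_movie()
  expect_true(all(mm$divided$division_length >=
                    mm$divided$sampled_division_length - 1e-9))
})

test_that("movies round-trip through TIFF/CSV/config files", {
  m <- simulate_movie(sim_params(seed = 2, n_founders = 1, n_frames = 3,
                                 field_px = c(120, 120)))
  d <- withr::local_tempdir()
  write_sim_movie(m, d)
  fr <- tiff::readTIFF(file.path(d, "frames.tif"), all = TRUE)
  expect_length(fr, 3)
  expect_equal(max(abs(fr[[1]] - m$frames[[1]])), 0, tolerance = 1e-4)
  cfg <- read_config(file.path(d, "params.cfg"))
  expect_equal(cfg$seed, 2L)
  expect_equal(cfg$cal_factor, 0.125)
  lt <- read.csv(file.path(d, "lineage_truth.csv"))
  expect_equal(nrow(lt), nrow(m$lineage_truth))
})
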