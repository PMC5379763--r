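mvdens <- function(pts, mu, S) {
  di <- det(S); Si <- solve(S)
  dx <- sweep(pts, 2, mu)
  q <- rowSums((dx %*% Si) * dx)
  exp(-q / 2) / (2 * pi * sqrt(di))
}

test_that("point clouds honour the budget and the apportionment rule", {
  set.seed(21)
  ## two pixels with distances (1, 3): allocation (N/4, 3N/4) +- 1
  px <- rbind(c(5, 5), c(5, 6))
  cl <- generate_points(px, c(1, 3), 100, dim_img = c(10, 10))
  expect_equal(cl$n_points, 100L)
  expect_equal(nrow(cl$points), 100)
  alloc <- tabulate(cl$gen_pixel, 2)
  expect_lte(abs(alloc[1] - 25), 1)
  expect_lte(abs(alloc[2] - 75), 1)
  expect_equal(sum(cl$pi), 1, tolerance = 1e-9)

  ## single pixel: sample mean within 3 * sqrt(sigma2 / N) of the pixel
  cl1 <- generate_points(matrix(c(7, 7), 1), 1, 400, dim_img = c(14, 14))
  expect_lt(max(abs(colMeans(cl1$points) - 7)), 3 * sqrt(0.3 / 400) + 0.05)

  ## rod object: density decreases away from the medial axis
  rod <- rod_mask(30, 60, 45, 9)
  dt <- matrix(as.numeric(EBImage::imageData(
    EBImage::distmap(EBImage::Image(rod * 1)))), 30, 60)
  pxr <- which(rod, arr.ind = TRUE)
  clr <- generate_points(pxr, dt[pxr], 4000, dim_img = c(30, 60))
  ddist <- abs(clr$points[, 1] - 15.5)       # distance to horizontal axis
  h <- hist(pmin(ddist, 4.4), breaks = c(0, 1, 2, 3, 4.5), plot = FALSE)$density
  expect_true(all(diff(h) < 0))
})

test_that("initialization recovers moments and the exact log-likelihood", {
  set.seed(22)
  pts <- cbind(rnorm(500, 10, 1), rnorm(500, 20, 1))
  init <- init_mixture(pts, matrix(c(10, 20), 1))
  expect_lt(max(abs(init$means - c(10, 20))), 3 / sqrt(500) + 0.05)

  pts2 <- rbind(cbind(rnorm(300, 0, 1), rnorm(300, 0, 1)),
                cbind(rnorm(300, 12, 1), rnorm(300, 12, 1)))
  init2 <- init_mixture(pts2, rbind(c(0, 0), c(12, 12)))
  expect_equal(init2$weights, c(0.5, 0.5), tolerance = 0.05)

  ## brute-force log-likelihood oracle
  brute <- sum(log(
    init2$weights[1] * mvdens(pts2, init2$means[1, ], init2$covs[[1]]) +
    init2$weights[2] * mvdens(pts2, init2$means[2, ], init2$covs[[2]])))
  expect_equal(init2$loglik, brute, tolerance = 1e-9)
})

test_that("EM with MML collapses redundant components on planted data", {
  ## 4 well-separated clusters, init C = 6 -> 4 components survive
  set.seed(23)
  ctr <- rbind(c(5, 5), c(5, 25), c(25, 5), c(25, 25))
  pts <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(400, ctr[k, 1], 1), rnorm(400, ctr[k, 2], 1))))
  init <- suppressWarnings(init_mixture(pts, pts[sample(nrow(pts), 7), ]))
  fit <- fit_gmm_mml(pts, init)
  expect_equal(fit$n_components, 4)
  expect_true(all(abs(fit$weights - 0.25) < 0.05))

  ## 1 cluster, init C = 3 -> collapses to 1 in most seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    p1 <- cbind(rnorm(400, 0, 1), rnorm(400, 0, 1))
    i1 <- suppressWarnings(init_mixture(p1, p1[sample(400, 3), ]))
    hits <- hits + (fit_gmm_mml(p1, i1)$n_components == 1)
  }
  expect_gte(hits, 9)
})

test_that("component count never increases and weights stay normalized", {
  set.seed(24)
  pts <- rbind(cbind(rnorm(300, 0, 1), rnorm(300, 0, 1)),
               cbind(rnorm(300, 8, 1), rnorm(300, 8, 1)))
  init <- suppressWarnings(init_mixture(pts, pts[sample(600, 5), ]))
  fit <- fit_gmm_mml(pts, init)
  expect_lte(fit$n_components, 5)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(vapply(fit$covs, function(S)
    S[1, 2] == S[2, 1] && det(S) > 0, logical(1))))
})

test_that("mclust agrees with the fitted means on well-separated clusters", {
  library(mclust)   # Mclust resolves helpers from the attached namespace
  set.seed(25)
  ctr <- rbind(c(0, 0), c(15, 0), c(0, 15))
  pts <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(300, ctr[k, 1], 1), rnorm(300, ctr[k, 2], 1))))
  km <- stats::kmeans(pts, centers = 6, nstart = 5)
  init <- suppressWarnings(init_mixture(pts, km$centers))
  fit <- fit_gmm_mml(pts, init)
  mc <- mclust::Mclust(pts, G = 1:6, verbose = FALSE)
  expect_equal(fit$n_components, mc$G)
  ours <- fit$means[order(fit$means[, 1], fit$means[, 2]), ]
  theirs <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1],
                                        t(mc$parameters$mean)[, 2]), ]
  expect_equal(ours, theirs, tolerance = 0.2, ignore_attr = TRUE)
})

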