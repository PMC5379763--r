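test_that("exponential length fits are exact on noiseless data", {
  t <- seq(0, 40, by = 5)
  l <- 2 * exp(0.02 * t)
  fit <- fit_exponential_growth(l, t)
  expect_equal(fit$l0, 2, tolerance = 1e-6)
  expect_equal(fit$k, 0.02, tolerance = 1e-6)
  ## constant series: k = 0
  fc <- fit_exponential_growth(rep(3, 6), seq(0, 25, by = 5))
  expect_equal(fc$k, 0, tolerance = 1e-8)
  expect_error(fit_exponential_growth(c(1, -1, 2), c(0, 1, 2)))
})

test_that("exponential rate recovery under multiplicative noise", {
  set.seed(31)
  t <- seq(0, 40, by = 5)
  khat <- replicate(500, {
    l <- 2 * exp(0.02 * t) * (1 + rnorm(length(t), 0, 0.03))
    fit_exponential_growth(l, t)$k
  })
  expect_lt(abs(median(khat) - 0.02) / 0.02, 0.02)
})

test_that("Baranyi-Roberts recovers lag and growth rate", {
  set.seed(32)
  t <- seq(0, 200, by = 5)
  truth <- list(y0 = log(3), mu = 0.03, lambda = 30)
  reps <- 60   # median over replicates; tolerance is the acceptance one
  est <- replicate(reps, {
    y <- truth$y0 + truth$mu * baranyi_adjustment(t, truth$mu, truth$lambda) +
      rnorm(length(t), 0, 0.02)
    f <- fit_baranyi_roberts(t, y)
    c(f$lambda_lag, f$mu_max)
  })
  expect_lt(abs(median(est[1, ]) - 30), 3)
  expect_lt(abs(median(est[2, ]) - 0.03) / 0.03, 0.05)

  ## pure exponential: estimated lag stays near zero
  y <- log(2) + 0.03 * t
  f0 <- fit_baranyi_roberts(t, y)
  expect_lte(f0$lambda_lag, 3)

  ## the fixed curvature makes the noiseless curve piecewise linear:
  ## before the lag the curve is flat, after it the slope is mu
  yy <- 1 + 0.03 * baranyi_adjustment(t, 0.03, 50)
  expect_lt(max(abs(yy[t <= 45] - 1)), 0.05)
  late <- t >= 60
  expect_equal(unname(coef(lm(yy[late] ~ t[late]))[2]), 0.03,
               tolerance = 1e-3)
})

test_that("life attributes follow their definitions", {
  node <- data.frame(cell_id = 7, fate = "divided", birth_frame = 10,
                     division_frame = 14, generation = 2)
  inst <- data.frame(frame = 10:14, cell_instant_id = 1:5,
                     length_um = 2 * exp(0.02 * seq(0, 20, by = 5)))
  la <- life_attributes(node, inst, sampling_period = 5)
  expect_equal(la$T_div, 20)
  expect_equal(la$E, log(la$lf / la$l0))
  expect_equal(la$k, 0.02, tolerance = 1e-6)
  expect_false(la$censored)
  ## lengths 2 -> 4: E = ln 2
  inst2 <- inst; inst2$length_um <- seq(2, 4, length.out = 5)
  expect_equal(life_attributes(node, inst2, 5)$E, log(2))
  ## censored cell flagged
  nodec <- node; nodec$fate <- "censored"
  expect_true(life_attributes(nodec, inst, 5)$censored)
})

test_that("E ~ k * T_div on simulated exponential growth", {
  set.seed(33)
  gaps <- replicate(200, {
    k <- rgamma(1, 25, scale = log(2) / 25 / 25)
    T_div <- 25 + runif(1, -5, 5)
    frames <- seq(0, T_div, by = 5)
    l <- 2.5 * exp(k * frames)
    E <- log(l[length(l)] / l[1])
    khat <- fit_exponential_growth(l, frames)$k
    abs(E - khat * (frames[length(frames)] - frames[1])) / E
  })
  expect_lt(median(gaps), 0.05)
})

test_that("gamma MLE matches truth and flags degenerate input", {
  set.seed(34)
  x <- rgamma(10000, shape = 4, scale = 2)
  f <- fit_gamma(x)
  expect_lt(abs(f$shape - 4) / 4, 0.05)
  expect_lt(abs(f$scale - 2) / 2, 0.05)
  ## exponential data: shape ~ 1
  e <- rgamma(5000, shape = 1, scale = 3)
  expect_lt(abs(fit_gamma(e)$shape - 1), 0.08)
  expect_error(fit_gamma(rep(2, 100)))
  expect_error(fit_gamma(c(-1, rexp(30))))
  expect_error(fit_gamma(rexp(10)))
})

test_that("Pearson correlation handles the sign conventions and degeneracy", {
  x <- 1:10
  expect_equal(pearson_corr(x, 2 * x), 1)
  expect_equal(pearson_corr(x, -x + 5), -1)
  expect_warning(r <- pearson_corr(x, rep(1, 10)))
  expect_true(is.na(r))
})

test_that("elongation anti-correlates with log birth length when division length is tight", {
  ## mechanism: lf nearly fixed => E = ln lf - ln l0 decreases in ln l0
  set.seed(35)
  l0 <- exp(rnorm(300, log(2.5), 0.15))
  lf <- rgamma(300, shape = 400, scale = 5 / 400)  # tight division length
  E <- log(lf / l0)
  expect_lt(pearson_corr(E, log(l0)), 0)
})
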