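## Data-cloud generation and Gaussian mixture fitting with minimum message
## length (MML) model selection. The object's pixels act as point
## generators weighted by their Euclidean distance-transform value, so the
## cloud is densest along cell medial axes; component-wise EM with the MML
## weight update annihilates superfluous components, and the surviving
## components are the segmented cells.

#' Generate the data cloud representing a complex object
#'
#' Each object pixel i with distance-transform value d_i receives a mixing
#' weight pi(i) = d_i / sum(d_j) and emits its share of the N points
#' (largest-remainder apportionment, so the shares sum to N exactly) from a
#' 2-D Gaussian centred at the pixel with covariance `sigma2 * I`. Draws
#' falling outside the image are clipped to the pixel's bounds.
#'
#' @param pixels (row, col) matrix of object pixels.
#' @param d distance-transform values at `pixels` (all > 0).
#' @param N total number of points (see [point_budget()]).
#' @param sigma2 per-pixel generator variance (default 0.3).
#' @param dim_img image dimensions c(nrow, ncol) for clipping.
#' @return list of class `data_cloud`: `points` (N x 2 matrix of (row, col)),
#'   `gen_pixel` (index into `pixels` of each point's generator), `pi`
#'   (per-pixel weights), `n_points`.
#' @export
generate_points <- function(pixels, d, N, sigma2 = 0.3, dim_img = NULL) {
  stopifnot(nrow(pixels) == length(d), all(d > 0), N >= 1)
  pi_i <- d / sum(d)
  ## largest-remainder apportionment: sum(n_i) = N exactly
  raw <- N * pi_i
  n_i <- floor(raw)
  rem <- N - sum(n_i)
  if (rem > 0) {
    o <- order(raw - n_i, decreasing = TRUE)
    n_i[o[seq_len(rem)]] <- n_i[o[seq_len(rem)]] + 1
  }
  gen <- rep(seq_len(nrow(pixels)), times = n_i)
  sdv <- sqrt(sigma2)
  pts <- cbind(pixels[gen, 1] + rnorm(length(gen), 0, sdv),
               pixels[gen, 2] + rnorm(length(gen), 0, sdv))
  ## clip out-of-image draws back to the generating pixel's bounds
  if (!is.null(dim_img)) {
    bad1 <- pts[, 1] < 0.5 | pts[, 1] > dim_img[1] + 0.5
    pts[bad1, 1] <- clamp(pts[bad1, 1], pixels[gen[bad1], 1] - 0.5,
                          pixels[gen[bad1], 1] + 0.5)
    bad2 <- pts[, 2] < 0.5 | pts[, 2] > dim_img[2] + 0.5
    pts[bad2, 2] <- clamp(pts[bad2, 2], pixels[gen[bad2], 2] - 0.5,
                          pixels[gen[bad2], 2] + 0.5)
  }
  structure(list(points = pts, gen_pixel = gen, pi = pi_i,
                 n_points = as.integer(N)),
            class = "data_cloud")
}

## log N(y; mu, Sigma) for all points, 2-D full covariance
log_dmvnorm2 <- function(pts, mu, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (det <= 0) return(rep(-Inf, nrow(pts)))
  inv11 <- S[2, 2] / det; inv22 <- S[1, 1] / det; inv12 <- -S[1, 2] / det
  dx <- pts[, 1] - mu[1]; dy <- pts[, 2] - mu[2]
  q <- inv11 * dx * dx + 2 * inv12 * dx * dy + inv22 * dy * dy
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Log-likelihood of a data set under a Gaussian mixture
#' @param pts n x 2 matrix.
#' @param model mixture with `means` (C x 2), `covs` (list of 2x2), `weights`.
#' @return total log-likelihood.
#' @export
gmm_loglik <- function(pts, model) {
  LD <- vapply(seq_along(model$weights), function(m)
    log_dmvnorm2(pts, model$means[m, ], model$covs[[m]]) +
      log(model$weights[m]),
    numeric(nrow(pts)))
  if (is.null(dim(LD))) LD <- matrix(LD, nrow = nrow(pts))
  mx <- apply(LD, 1, max)
  sum(mx + log(rowSums(exp(LD - mx))))
}

#' Initialize a mixture from candidate centres
#'
#' Hard-assigns every point to its nearest candidate centre (Euclidean
#' nearest-neighbour classification); each component takes the sample mean
#' and covariance of its points (ridge-regularized by 1e-4 I) and a weight
#' equal to its point fraction. Empty components are dropped with a warning.
#'
#' @param cloud a [generate_points()] cloud (or any n x 2 matrix).
#' @param centers C x 2 matrix of candidate centres (row, col).
#' @return mixture model list: `means`, `covs`, `weights`, `loglik`,
#'   `n_components`.
#' @export
init_mixture <- function(cloud, centers) {
  pts <- if (inherits(cloud, "data_cloud")) cloud$points else cloud
  centers <- matrix(centers, ncol = 2)
  d2 <- outer(pts[, 1], centers[, 1], `-`)^2 +
        outer(pts[, 2], centers[, 2], `-`)^2
  assign <- max.col(-d2, ties.method = "first")
  keep <- sort(unique(assign))
  if (length(keep) < nrow(centers))
    warning(sprintf("%d empty component(s) dropped before EM",
                    nrow(centers) - length(keep)))
  means <- matrix(0, length(keep), 2)
  covs <- vector("list", length(keep))
  w <- numeric(length(keep))
  for (i in seq_along(keep)) {
    p <- pts[assign == keep[i], , drop = FALSE]
    means[i, ] <- colMeans(p)
    S <- if (nrow(p) > 1) stats::cov(p) else diag(2) * 0.3
    covs[[i]] <- S + diag(2) * 1e-4
    w[i] <- nrow(p) / nrow(pts)
  }
  model <- list(means = means, covs = covs, weights = w,
                n_components = length(keep))
  model$loglik <- gmm_loglik(pts, model)
  model
}

#' Fit a Gaussian mixture with MML-based component annihilation
#'
#' Component-wise EM: each component in turn is re-estimated from its
#' responsibilities, its weight updated by the MML rule
#' `w_m proportional to max(0, n_m - n_par/2)` (n_par = 5 free parameters for a
#' 2-D full-covariance component) and annihilated when the weight reaches
#' zero; the weighted-density column of the updated component is then
#' refreshed. The objective is the message length
#' `L = n_par/2 * sum_m log(N w_m / 12) + C/2 * log(N/12) + C (n_par+1)/2 - loglik`,
#' which decreases across accepted iterations; convergence at relative
#' change < 1e-5 (at most `max_iter` sweeps). If every component is
#' annihilated, a single-component fit is returned.
#'
#' @param cloud a [generate_points()] cloud or n x 2 point matrix.
#' @param init initial mixture from [init_mixture()].
#' @param max_iter maximum EM sweeps.
#' @param tol relative message-length tolerance.
#' @param patience stop the model-selection descent after this many
#'   consecutive non-improving component removals.
#' @param cov_floor lower bound on component covariance eigenvalues. No real
#'   structure can be tighter than the resolution of the data (for
#'   generated clouds, the per-pixel generator variance), and the floor
#'   prevents degenerate high-likelihood slivers.
#' @return fitted mixture: `means`, `covs`, `weights`, `n_components`,
#'   `loglik`, `message_length`, `assign` (per-point component),
#'   `trace` (message length per accepted sweep).
#' @export
fit_gmm_mml <- function(cloud, init, max_iter = 200, tol = 1e-5,
                        patience = 2, cov_floor = 0.25) {
  pts <- if (inherits(cloud, "data_cloud")) cloud$points else cloud
  N <- nrow(pts)
  npar <- 5

  msg_len <- function(logS, w) {
    Cnz <- length(w)
    npar / 2 * sum(log(N * w / 12)) + Cnz / 2 * log(N / 12) +
      Cnz * (npar + 1) / 2 - sum(logS)
  }
  row_logsum <- function(LD, w) {
    LW <- sweep(LD, 2, log(w), `+`)
    mx <- apply(LW, 1, max)
    list(logS = mx + log(rowSums(exp(LW - mx))), LW = LW)
  }

  ## component-wise EM sweeps with starvation-based annihilation, run to
  ## convergence of the message length. Densities are kept in linear space
  ## (the covariance floor bounds them) and the mixture row sums are
  ## maintained incrementally, so a full sweep costs O(N C).
  cem_converge <- function(st) {
    tiny <- 1e-300
    L_prev <- Inf
    S <- as.vector(st$D %*% st$w)
    for (iter in seq_len(max_iter)) {
      m <- 1
      while (m <= length(st$w)) {
        wm <- st$w[m]
        resp <- wm * st$D[, m] / pmax(S, tiny)
        n_m <- sum(resp)
        if (n_m <= npar) {
          if (length(st$w) == 1) break
          S <- (S - wm * st$D[, m]) / (1 - wm)
          st$means <- st$means[-m, , drop = FALSE]
          st$covs <- st$covs[-m]
          st$w <- st$w[-m] / (1 - wm)
          st$D <- st$D[, -m, drop = FALSE]
          next
        }
        mu <- c(sum(resp * pts[, 1]), sum(resp * pts[, 2])) / n_m
        dx <- pts[, 1] - mu[1]; dy <- pts[, 2] - mu[2]
        Sg <- matrix(c(sum(resp * dx * dx), sum(resp * dx * dy),
                       sum(resp * dx * dy), sum(resp * dy * dy)) / n_m, 2, 2)
        Sg <- Sg + diag(2) * 1e-4
        eg <- eigen(Sg, symmetric = TRUE)
        if (any(eg$values < cov_floor)) {
          ev <- pmax(eg$values, cov_floor)
          Sg <- eg$vectors %*% diag(ev) %*% t(eg$vectors)
        }
        st$means[m, ] <- mu; st$covs[[m]] <- Sg
        Dm_new <- exp(log_dmvnorm2(pts, mu, Sg))
        ## MML weight update; remaining weights rescaled proportionally
        wm_new <- max(0, n_m - npar / 2) /
          max(nrow(pts) - length(st$w) * npar / 2, 1)
        wm_new <- min(wm_new, 1 - 1e-12)
        scale <- (1 - wm_new) / max(1 - wm, 1e-12)
        S <- scale * (S - wm * st$D[, m]) + wm_new * Dm_new
        st$w <- st$w * scale
        st$w[m] <- wm_new
        st$D[, m] <- Dm_new
        m <- m + 1
      }
      st$w <- st$w / sum(st$w)
      S <- as.vector(st$D %*% st$w)   # refresh against drift
      logS <- log(pmax(S, tiny))
      L_now <- msg_len(logS, st$w)
      if (is.finite(L_prev) && abs(L_prev - L_now) < tol * abs(L_prev)) break
      L_prev <- L_now
    }
    S <- as.vector(st$D %*% st$w)
    st$logS <- log(pmax(S, tiny))
    st$L <- msg_len(st$logS, st$w)
    st
  }

  st <- list(means = init$means, covs = init$covs, weights = NULL,
             w = init$weights)
  st$D <- vapply(seq_along(st$w), function(m)
    exp(log_dmvnorm2(pts, st$means[m, ], st$covs[[m]])), numeric(N))
  if (is.null(dim(st$D))) st$D <- matrix(st$D, nrow = N)

  st <- cem_converge(st)
  best <- st
  trace <- st$L
  ## model-selection descent: force-annihilate the weakest component,
  ## re-converge, and keep the minimum-message-length model
  fails <- 0
  while (length(st$w) > 1 && fails < patience) {
    drop <- which.min(st$w)
    st$means <- st$means[-drop, , drop = FALSE]
    st$covs <- st$covs[-drop]
    st$w <- st$w[-drop] / sum(st$w[-drop])
    st$D <- st$D[, -drop, drop = FALSE]
    st <- cem_converge(st)
    trace <- c(trace, st$L)
    if (st$L < best$L) { best <- st; fails <- 0 } else fails <- fails + 1
  }
  assign <- max.col(sweep(best$D, 2, best$w, `*`), ties.method = "first")
  list(means = best$means, covs = best$covs, weights = best$w,
       n_components = length(best$w), loglik = sum(best$logS),
       message_length = best$L, assign = assign, trace = trace)
}

## Assign object pixels to mixture components: majority vote over the points
## each pixel generated; point-less pixels take the component with maximal
## weighted density at the pixel centre.
assign_pixels <- function(pixels, cloud, fit) {
  votes <- tapply(fit$assign, cloud$gen_pixel, function(a)
    as.integer(names(which.max(table(a)))))
  out <- rep(NA_integer_, nrow(pixels))
  out[as.integer(names(votes))] <- unname(votes)
  if (anyNA(out)) {
    idx <- which(is.na(out))
    LD <- vapply(seq_along(fit$weights), function(m)
      log_dmvnorm2(pixels[idx, , drop = FALSE], fit$means[m, ],
                   fit$covs[[m]]) + log(fit$weights[m]),
      numeric(length(idx)))
    if (is.null(dim(LD))) LD <- matrix(LD, nrow = length(idx))
    out[idx] <- max.col(LD, ties.method = "first")
  }
  out
}
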