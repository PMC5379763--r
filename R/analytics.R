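## Single-cell and population growth analytics: exponential elongation fits,
## Baranyi-Roberts population kinetics, life attributes, gamma distribution
## fits and correlation utilities.

#' Fit the exponential single-cell length model
#'
#' Nonlinear least squares for `l(t) = l0 * exp(k t)`, initialized from the
#' log-linear regression of `log(l)` on `t`.
#'
#' @param lengths cell lengths (um), all positive.
#' @param times observation times (min).
#' @return list with `l0`, `k`, `rss`, `n`.
#' @export
fit_exponential_growth <- function(lengths, times) {
  stopifnot(length(lengths) == length(times), length(lengths) >= 2)
  if (any(lengths <= 0)) stop("non-positive lengths")
  ll <- lm(log(lengths) ~ times)
  l0_0 <- unname(exp(coef(ll)[1])); k_0 <- unname(coef(ll)[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(lengths ~ l0 * exp(k * times),
                      start = list(l0 = l0_0, k = k_0),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- l0_0 * exp(k_0 * times)
    return(list(l0 = unname(l0_0), k = unname(k_0),
                rss = sum((lengths - pred)^2), n = length(lengths)))
  }
  cf <- coef(fit)
  list(l0 = unname(cf["l0"]), k = unname(cf["k"]),
       rss = sum(residuals(fit)^2), n = length(lengths))
}

#' Baranyi-Roberts lag-adjustment function
#'
#' `A(t) = t + 1/(n mu) * ln(exp(-n mu t) + exp(-n mu lambda)
#'  - exp(-n mu (t + lambda)))`; with curvature `n` fixed at 20 the model
#' transitions abruptly from the lag to the exponential phase, and `m = 0`
#' disables stationary-phase damping. Computed in log-space for stability.
#'
#' @param t time (min).
#' @param mu_max maximum specific growth rate (1/min).
#' @param lambda lag time (min).
#' @param n curvature parameter.
#' @return A(t), same length as `t`.
#' @export
baranyi_adjustment <- function(t, mu_max, lambda, n = 20) {
  a <- -n * mu_max * t
  b <- -n * mu_max * lambda
  mx <- pmax(a, b)
  inner <- exp(a - mx) + exp(b - mx) - exp(a + b - mx)
  inner[inner <= 0] <- .Machine$double.xmin
  t + (mx + log(inner)) / (n * mu_max)
}

#' Fit the Baranyi-Roberts primary growth model
#'
#' Least squares of `y(t) = y0 + mu_max * A(t)` on log cell counts, with the
#' curvature parameters fixed (`m = 0`, `n = 20`). Parameters estimated:
#' `y0` (initial log count), `mu_max` (1/min), `lambda` (lag, min).
#'
#' @param times times (min), >= 8 points.
#' @param log_counts natural-log cell counts of one colony track.
#' @param n curvature (fixed, default 20).
#' @return list of class `baranyi_fit`: `y0`, `mu_max`, `lambda_lag`, `rss`,
#'   `m`, `n`, `n_obs`, `flag` ("ok" or "large-rss").
#' @export
fit_baranyi_roberts <- function(times, log_counts, n = 20) {
  stopifnot(length(times) == length(log_counts), length(times) >= 8)
  slope <- diff(log_counts) / diff(times)
  mu0 <- max(slope[is.finite(slope)], 1e-4)
  y00 <- log_counts[1]
  lam_grid <- seq(0, max(times) * 0.8, length.out = 17)
  best <- NULL
  for (lam0 in lam_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        log_counts ~ y0 + mu * baranyi_adjustment(times, mu, lambda, n = n),
        start = list(y0 = y00, mu = mu0, lambda = lam0),
        lower = c(y0 = -Inf, mu = 1e-6, lambda = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- coef(fit)
      best <- list(y0 = unname(cf["y0"]), mu_max = unname(cf["mu"]),
                   lambda_lag = unname(cf["lambda"]), rss = rss)
    }
  }
  if (is.null(best)) stop("Baranyi-Roberts fit failed on all starts")
  tot <- sum((log_counts - mean(log_counts))^2)
  best$m <- 0; best$n <- n; best$n_obs <- length(times)
  best$flag <- if (tot > 0 && best$rss / tot > 0.2) "large-rss" else "ok"
  class(best) <- "baranyi_fit"
  best
}

#' Life attributes of one cell
#'
#' Division time `T_div = (division_frame - birth_frame) * sampling_period`,
#' birth/division lengths `l0`/`lf`, elongation `E = ln(lf / l0)`,
#' elongation rate `k` from [fit_exponential_growth()], and min/max/mean/
#' median/sd summaries of each per-frame attribute. Cells whose life is
#' truncated by the movie (fate != "divided") are flagged censored and are
#' excluded from life-attribute distributions downstream.
#'
#' @param node one row of `lineage_forest$nodes`.
#' @param instants per-frame attribute rows of this cell (needs `frame` and
#'   `length_um`; other numeric columns are summarized).
#' @param sampling_period minutes per frame.
#' @return list of class `cell_life`: T_div, l0, lf, E, k, censored,
#'   `summaries` (per-attribute stats).
#' @export
life_attributes <- function(node, instants, sampling_period = 1) {
  stopifnot(nrow(instants) >= 1)
  instants <- instants[order(instants$frame), ]
  censored <- !identical(node$fate, "divided")
  T_div <- if (censored) NA_real_ else
    (node$division_frame - node$birth_frame) * sampling_period
  l <- instants$length_um
  l0 <- l[1]; lf <- l[length(l)]
  E <- log(lf / l0)
  k <- if (nrow(instants) >= 2) {
    t <- (instants$frame - instants$frame[1]) * sampling_period
    fit_exponential_growth(l, t)$k
  } else NA_real_
  num_cols <- names(instants)[vapply(instants, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("frame", "cell_instant_id", "cell_id",
                                  "colony_id", "colony_track_id"))
  summaries <- lapply(instants[num_cols], function(v)
    c(min = min(v), max = max(v), mean = mean(v), median = median(v),
      sd = if (length(v) > 1) sd(v) else NA_real_))
  structure(list(cell_id = node$cell_id, T_div = T_div, l0 = l0, lf = lf,
                 E = E, k = k, censored = censored, summaries = summaries),
            class = "cell_life")
}

#' Life-attribute table for a whole lineage forest
#'
#' @param forest a [track_cells()] result.
#' @param cells cell-instant table (from `segment_movie()$cells`).
#' @return data.frame, one row per cell: T_div, l0, lf, E, k, generation,
#'   colony_track_id, censored.
#' @export
life_attribute_table <- function(forest, cells) {
  inst <- merge(forest$instants, cells,
                by = c("frame", "cell_instant_id"), sort = FALSE)
  out <- lapply(seq_len(nrow(forest$nodes)), function(i) {
    node <- forest$nodes[i, ]
    ci <- inst[inst$cell_id == node$cell_id, ]
    if (nrow(ci) == 0) return(NULL)
    la <- life_attributes(node, ci, forest$sampling_period)
    data.frame(cell_id = node$cell_id,
               colony_track_id = node$colony_track_id,
               generation = node$generation,
               T_div = la$T_div, l0 = la$l0, lf = la$lf, E = la$E, k = la$k,
               censored = la$censored)
  })
  do.call(rbind, out)
}

#' Maximum-likelihood gamma fit of a life attribute
#'
#' @param values positive values, at least 20.
#' @return list of class `gamma_fit`: `shape`, `scale`, `n_obs`,
#'   `log_likelihood`.
#' @export
fit_gamma <- function(values) {
  if (length(values) < 20) stop("need at least 20 observations")
  if (any(values <= 0)) stop("non-positive values")
  if (sd(values) < 1e-12 * mean(values)) stop("degenerate (constant) data")
  ft <- fitdistrplus::fitdist(as.numeric(values), "gamma", method = "mle")
  structure(list(shape = unname(ft$estimate["shape"]),
                 scale = 1 / unname(ft$estimate["rate"]),
                 n_obs = length(values),
                 log_likelihood = ft$loglik),
            class = "gamma_fit")
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (n >= 3). Returns NA with a
#'   warning when either input has zero variance.
#' @return r in \[-1, 1\] (or NA).
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}
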