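#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Standard (mu/mu_w, lambda) CMA-ES minimizer: rank-based recombination
#' of the best half of each sampled population, cumulative step-size
#' adaptation, and rank-one plus rank-mu covariance updates. Implemented
#' here because no CMA-ES package ships with the supported environment;
#' the strategy parameters follow the standard tutorial formulation.
#'
#' Non-finite candidate costs are replaced by a large finite penalty and
#' logged, so a brittle objective cannot derail the ranking.
#'
#' @param fn objective function, numeric vector -> scalar cost.
#' @param x0 initial mean (numeric vector).
#' @param sigma initial step size (> 0).
#' @param lambda population size (>= 2).
#' @param max_generations generation budget.
#' @param stop_window window (generations) for the moving-average stopping
#'   rule; stopping triggers once the window average of the best cost
#'   improves by less than `stop_tol` relative to the previous window.
#' @param stop_tol improvement threshold.
#' @param lower,upper optional box bounds; samples are clipped before
#'   evaluation.
#' @param penalty cost assigned to non-finite evaluations.
#' @return list with `x_best`, `f_best`, `history` (data frame per
#'   generation: best, mean cost), `generations`, `stopped_by`
#'   (`"max_generations"` or `"window"`), `n_nonfinite`.
#' @export
cma_es <- function(fn, x0, sigma = 1, lambda = 16,
                   max_generations = 200,
                   stop_window = 500, stop_tol = 1e-4,
                   lower = NULL, upper = NULL,
                   penalty = 1e12) {
  n <- length(x0)
  stopifnot(lambda >= 2, sigma > 0, n >= 1)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- as.numeric(x0)
  C <- diag(n)
  B <- diag(n)
  D <- rep(1, n)
  pc <- ps <- rep(0, n)
  eigen_stale <- 0

  best_f <- Inf
  best_x <- xmean
  hist_best <- hist_mean <- numeric(0)
  n_nonfinite <- 0L
  stopped_by <- "max_generations"

  for (g in seq_len(max_generations)) {
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                       # N(0, C) samples
    X <- xmean + sigma * Y
    if (!is.null(lower)) X <- pmax(X, lower)
    if (!is.null(upper)) X <- pmin(X, upper)
    f <- apply(X, 2, fn)
    bad <- !is.finite(f)
    if (any(bad)) {
      n_nonfinite <- n_nonfinite + sum(bad)
      f[bad] <- penalty
    }
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- X[, ord[1]]
    }
    hist_best <- c(hist_best, f[ord[1]])
    hist_mean <- c(hist_mean, mean(f))

    sel <- ord[seq_len(mu)]
    yw <- (X[, sel, drop = FALSE] - xmean) %*% w / sigma
    xmean <- xmean + sigma * as.numeric(yw)

    Cinv_sqrt_y <- B %*% ((1 / D) * crossprod(B, yw))
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinv_sqrt_y)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * g)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc +
      (if (hsig) sqrt(cc * (2 - cc) * mueff) else 0) * as.numeric(yw)

    # deviations wrt the PRE-update mean
    artmp <- (X[, sel, drop = FALSE] -
                (xmean - sigma * as.numeric(yw))) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (if (!hsig) cc * (2 - cc) else 0) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    eigen_stale <- eigen_stale + 1
    if (eigen_stale >= max(1, floor(1 / ((c1 + cmu) * n * 10)))) {
      eigen_stale <- 0
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
    }

    if (g > 2 * stop_window) {
      prev <- mean(hist_best[(g - 2 * stop_window + 1):(g - stop_window)])
      curr <- mean(hist_best[(g - stop_window + 1):g])
      if (prev - curr < stop_tol) {
        stopped_by <- "window"
        break
      }
    }
  }
  list(x_best = best_x, f_best = best_f,
       history = data.frame(generation = seq_along(hist_best),
                            best = hist_best, mean = hist_mean),
       generations = length(hist_best),
       stopped_by = stopped_by, n_nonfinite = n_nonfinite)
}
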