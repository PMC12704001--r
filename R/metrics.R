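#' Gait metrics and adaptation-curve analysis
#'
#' Event-indexed step metrics (step lengths, step times, step velocities),
#' the step length/velocity asymmetry series, the spatial-temporal
#' decomposition of adaptation (center-of-oscillation difference and limb
#' phasing), exponential adaptation-curve fitting, and waveform similarity
#' measures (NCC, RMSE).
#'
#' @name gait_metrics
NULL

#' Step lengths and step times from a gait-event series
#'
#' Walks the heel-strike events (which must strictly alternate legs): at
#' each heel strike the step length is the striking (leading) foot position
#' minus the contralateral (trailing) stance-foot position at that instant,
#' and the step time is the interval since the contralateral heel strike.
#'
#' @param events event data frame with columns `time`, `leg`, `event`
#'   (`"HS"`/`"TO"`), `foot_pos`, `other_foot_pos` (as produced by
#'   [gait_events()]).
#' @return data frame with one row per step: `time`, `leg`,
#'   `step_length_m`, `step_time_s`, `step_velocity_mps`.
#' @export
step_lengths_and_times <- function(events) {
  hs <- events[events$event == "HS", , drop = FALSE]
  hs <- hs[order(hs$time), , drop = FALSE]
  if (nrow(hs) < 2L) stop("need at least 2 alternating heel strikes")
  same <- which(hs$leg[-1L] == hs$leg[-nrow(hs)])
  if (length(same)) {
    stop(sprintf("heel strikes do not alternate at event index %d", same[1] + 1L))
  }
  i <- 2:nrow(hs)
  data.frame(time = hs$time[i], leg = hs$leg[i],
             step_length_m = hs$foot_pos[i] - hs$other_foot_pos[i],
             step_time_s = hs$time[i] - hs$time[i - 1L],
             step_velocity_mps = (hs$foot_pos[i] - hs$other_foot_pos[i]) /
               (hs$time[i] - hs$time[i - 1L]),
             stringsAsFactors = FALSE)
}

#' Step length asymmetry
#'
#' `SLA = (l_fast - l_slow) / (l_fast + l_slow)`: the primary adaptation
#' readout, negative when the fast-belt step is shorter.
#'
#' @param l_fast,l_slow step lengths, meters (sum must be non-zero).
#' @return dimensionless asymmetry.
#' @export
sla <- function(l_fast, l_slow) {
  den <- l_fast + l_slow
  if (any(den == 0)) stop("l_fast + l_slow must be non-zero")
  (l_fast - l_slow) / den
}

#' Center-of-oscillation difference per stride
#'
#' The spatial component of adaptation. A leg's center of oscillation in a
#' stride is the mean of its limb angle at heel strike and at toe-off; the
#' reported value is slow-leg minus fast-leg, in degrees (0 for symmetric
#' walking).
#'
#' @param events event data frame with columns `stride`, `leg`, `event`,
#'   `limb_angle` (radians).
#' @return data frame `(stride, coo_diff_deg)`.
#' @export
center_of_oscillation_difference <- function(events) {
  strides <- sort(unique(events$stride))
  coo <- function(str, leg) {
    sel <- events$stride == str & events$leg == leg
    hs <- events$limb_angle[sel & events$event == "HS"]
    to <- events$limb_angle[sel & events$event == "TO"]
    if (length(hs) < 1L || length(to) < 1L) {
      stop(sprintf("stride %s, %s leg: missing HS or TO limb angle", str, leg))
    }
    mean(c(hs[1], to[1]))
  }
  diff_deg <- vapply(strides, function(s) {
    (coo(s, "slow") - coo(s, "fast")) * 180 / pi
  }, 0)
  data.frame(stride = strides, coo_diff_deg = diff_deg)
}

circular_xcorr <- function(x, y) {
  # r[k+1] = sum_i xc[i] * yc[i + k (mod n)]  via FFT
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  Re(stats::fft(stats::fft(yc) * Conj(stats::fft(xc)), inverse = TRUE)) / n
}

#' Limb phasing (temporal component)
#'
#' The lag, as a fraction of the stride in [0, 1), at which the circular
#' cross-correlation of the mean-removed fast and slow limb-angle traces
#' peaks, with the slow leg as the reference. Perfect alternation gives
#' 0.5; identical in-phase traces give 0.
#'
#' @param theta_fast,theta_slow limb-angle traces over one stride, radians,
#'   equal length, common sample period.
#' @param stride_duration stride duration, s (only used to express the
#'   resolution; the returned phasing is the lag in samples over the trace
#'   length).
#' @return phasing fraction in [0, 1).
#' @export
limb_phasing <- function(theta_fast, theta_slow, stride_duration = NULL) {
  if (length(theta_fast) != length(theta_slow)) {
    stop("limb-angle traces must have equal length")
  }
  n <- length(theta_fast)
  if (n < 2L) stop("traces too short")
  r <- circular_xcorr(theta_slow, theta_fast)
  (which.max(r) - 1L) / n
}

#' Exponential adaptation-curve fit
#'
#' Nonlinear least squares fit of `y = a - b * exp(-s / c)` over the stride
#' number `s` (1-based): `c` quantifies the adaptation rate (strides) and
#' `|b|` the amount of adaptation. Multi-start over
#' `c in {2, 5, 10, 20, 40}` with `a`, `b` initialized from the series
#' endpoints guards against local minima; each start tries `nls` (port
#' algorithm, `c > 0`) and falls back to Nelder-Mead on the residual sum
#' of squares. Reports `converged = FALSE` rather than failing.
#'
#' @param series numeric vector (the per-stride quantity), or a data frame
#'   with columns `s` and `y`; length >= 4.
#' @param c_starts initial guesses for the rate parameter.
#' @return object of class `exp_fit`: list with `a`, `b`, `c`,
#'   `residual_norm`, `converged`, `fitted`.
#' @export
fit_exponential <- function(series, c_starts = c(2, 5, 10, 20, 40)) {
  if (is.data.frame(series)) {
    s <- series$s
    y <- series$y
  } else {
    y <- as.numeric(series)
    s <- seq_along(y)
  }
  if (length(y) < 4L) stop("series must have length >= 4")

  rss <- function(p) sum((y - (p[1] - p[2] * exp(-s / p[3])))^2)
  best <- NULL
  for (c0 in c_starts) {
    a0 <- mean(utils::tail(y, max(1L, length(y) %/% 5L)))
    b0 <- (a0 - y[1]) * exp(min(s) / c0)
    fit <- tryCatch({
      m <- stats::nls(y ~ a - b * exp(-s / cc),
                      data = data.frame(s = s, y = y),
                      start = list(a = a0, b = b0, cc = c0),
                      algorithm = "port",
                      lower = c(a = -Inf, b = -Inf, cc = 1e-6),
                      control = stats::nls.control(maxiter = 200, warnOnly = FALSE))
      p <- stats::coef(m)
      list(par = c(p[["a"]], p[["b"]], p[["cc"]]), value = rss(c(p[["a"]], p[["b"]], p[["cc"]])))
    }, error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch({
        o <- stats::optim(c(a0, b0, c0), function(p) {
          if (p[3] <= 0) return(1e12)
          rss(p)
        }, method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-12))
        list(par = o$par, value = o$value)
      }, error = function(e) NULL)
    }
    if (!is.null(fit) && is.finite(fit$value) && fit$par[3] > 0 &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          fitted = rep(NA_real_, length(y))),
                     class = "exp_fit"))
  }
  p <- best$par
  structure(list(a = p[1], b = p[2], c = p[3],
                 residual_norm = sqrt(best$value), converged = TRUE,
                 fitted = p[1] - p[2] * exp(-s / p[3])),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Exponential fit: did not converge\n")
  } else {
    cat(sprintf("Exponential fit y = a - b*exp(-s/c): a = %.5g, b = %.5g, c = %.5g\n",
                x$a, x$b, x$c))
    cat(sprintf("  residual norm %.4g; |b| (amount) %.4g, c (rate, strides) %.4g\n",
                x$residual_norm, abs(x$b), x$c))
  }
  invisible(x)
}

#' Normalized cross-correlation at zero lag
#'
#' Mean-removed, unit-normalized similarity of two equal-length waveforms;
#' 1 for identical shapes (any offset), -1 for sign-flipped shapes.
#'
#' @param x,y numeric vectors, equal length >= 2.
#' @return scalar in [-1, 1].
#' @export
ncc <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 2L) stop("inputs too short")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Root-mean-squared error
#'
#' @param x,y numeric vectors, equal length >= 2.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 2L) stop("inputs too short")
  sqrt(mean((x - y)^2))
}

#' Stride-by-stride average across parallel runs
#'
#' Averages a per-stride series across runs of possibly different lengths:
#' when lengths differ, only the final stride(s) of longer runs are
#' dropped so that every averaged stride has at least two contributors.
#'
#' @param series_list list of numeric vectors (one per run).
#' @return data frame `(stride, mean, sd, n)`.
#' @export
average_stride_series <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  lens <- lengths(series_list)
  keep <- if (length(series_list) == 1L) lens else sort(lens, decreasing = TRUE)[2]
  n_str <- min(max(lens), keep)
  out <- lapply(seq_len(n_str), function(k) {
    vals <- unlist(lapply(series_list, function(x) if (length(x) >= k) x[k] else NULL))
    data.frame(stride = k, mean = mean(vals),
               sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
               n = length(vals))
  })
  do.call(rbind, out)
}
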