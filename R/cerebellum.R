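#' Cerebellar adaptation layer
#'
#' The supraspinal layer maintains an internal prediction of the step
#' velocity asymmetry (SVA), compares it with the observed SVA shortly after
#' every heel strike, and descends the gradient of the squared prediction
#' error: the prediction moves toward the observation at learning rate
#' `alpha`, and the two swing-initiation thresholds of the spinal state
#' machine move along the per-leg error gradients at adaptation rate `beta`.
#'
#' @name cerebellum
NULL

#' Create a cerebellar state
#'
#' @param alpha learning rate for the internal SVA prediction (dimensionless,
#'   >= 0). Governs how fast the prediction tracks the observed asymmetry.
#' @param beta adaptation rate for the swing-initiation thresholds (seconds
#'   per unit error gradient, >= 0).
#' @param t_fast,t_slow initial swing-initiation thresholds, seconds: the
#'   delay after a leg's own heel strike at which that leg transitions from
#'   mid-stance to pre-swing.
#' @param sva_pred initial internal prediction; 0 corresponds to symmetric
#'   tied-belt walking where no adaptation occurs.
#' @param convention gradient convention for the per-leg threshold updates:
#'   `"printed"` uses the published closed-form partial derivatives of the
#'   error with respect to the two step velocities; `"analytic"` uses the
#'   chain-rule derivative of the squared-error/asymmetry composition. The
#'   two differ by a sign on the slow-leg gradient (see
#'   [error_gradients()]).
#' @param sensitivity signed sensitivity factor(s) mapping the SV-space
#'   gradient onto the threshold update, one value or a named pair
#'   `c(fast = , slow = )`. `+1` applies the gradient as printed (implicit
#'   unit Jacobian dSV/dt = +1); `-1` flips it for plants in which a longer
#'   stance shortens the step velocity. The package default is the
#'   configuration under which the closed loop with [surrogate_plant()]
#'   reduces the error over strides.
#' @param t_bounds clipping bounds for the thresholds, seconds. Defaults to
#'   `c(0.05, 1)` to prevent degenerate stance phases.
#' @return an object of class `cerebellar_state`.
#' @seealso [on_heel_strike()], [run_closed_loop()]
#' @export
cerebellar_state <- function(alpha = 0.002, beta = 0.02,
                             t_fast = 0.35, t_slow = 0.35,
                             sva_pred = 0,
                             convention = c("analytic", "printed"),
                             sensitivity = c(fast = 1, slow = 1),
                             t_bounds = c(0.05, 1)) {
  convention <- match.arg(convention)
  stopifnot(is.finite(alpha), alpha >= 0,
            is.finite(beta), beta >= 0,
            is.finite(sva_pred),
            length(t_bounds) == 2L, t_bounds[1] < t_bounds[2])
  if (length(sensitivity) == 1L) {
    sensitivity <- c(fast = unname(sensitivity), slow = unname(sensitivity))
  }
  if (is.null(names(sensitivity)) || !setequal(names(sensitivity), c("fast", "slow"))) {
    names(sensitivity) <- c("fast", "slow")
  }
  if (t_fast < t_bounds[1] || t_fast > t_bounds[2] ||
      t_slow < t_bounds[1] || t_slow > t_bounds[2]) {
    stop("initial thresholds must lie within t_bounds")
  }
  structure(list(sva_pred = sva_pred, alpha = alpha, beta = beta,
                 t_fast = t_fast, t_slow = t_slow,
                 convention = convention,
                 sensitivity = sensitivity[c("fast", "slow")],
                 t_bounds = t_bounds),
            class = "cerebellar_state")
}

#' @export
print.cerebellar_state <- function(x, ...) {
  cat("Cerebellar state\n")
  cat(sprintf("  sva_pred: %.6g   alpha: %.4g   beta: %.4g\n",
              x$sva_pred, x$alpha, x$beta))
  cat(sprintf("  thresholds [s]: t_fast = %.4g, t_slow = %.4g (clip [%.3g, %.3g])\n",
              x$t_fast, x$t_slow, x$t_bounds[1], x$t_bounds[2]))
  cat(sprintf("  gradient convention: %s; sensitivity fast %+g, slow %+g\n",
              x$convention, x$sensitivity[["fast"]], x$sensitivity[["slow"]]))
  invisible(x)
}

#' Step velocity
#'
#' Step velocity of one leg: the ratio of its step length to its step time.
#'
#' @param l step length, meters.
#' @param d step time, seconds (> 0): the interval from the contralateral
#'   heel strike to the leg's own heel strike.
#' @return step velocity, m/s.
#' @export
step_velocity <- function(l, d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("step time d must be positive")
  l / d
}

#' Step velocity asymmetry
#'
#' Normalized difference of the fast- and slow-leg step velocities,
#' `(sv_fast - sv_slow) / (sv_fast + sv_slow)`. Bounded in [-1, 1] for
#' non-negative inputs; zero for symmetric walking. This is the error signal
#' the cerebellar layer predicts and cancels.
#'
#' @param sv_fast,sv_slow step velocities, m/s.
#' @return dimensionless asymmetry.
#' @export
step_velocity_asymmetry <- function(sv_fast, sv_slow) {
  den <- sv_fast + sv_slow
  if (any(den == 0)) stop("sv_fast + sv_slow must be non-zero")
  (sv_fast - sv_slow) / den
}

#' Sensorimotor prediction error
#'
#' Half squared difference between the internal SVA prediction and the
#' observed SVA: `e = 0.5 * (sva_pred - sva)^2`.
#'
#' @param sva_pred internal prediction.
#' @param sva observed step velocity asymmetry.
#' @return error, >= 0, zero iff prediction matches observation.
#' @export
prediction_error <- function(sva_pred, sva) {
  0.5 * (sva_pred - sva)^2
}

#' Gradients of the prediction error
#'
#' Partial derivatives of the prediction error with respect to the slow and
#' fast step velocities and to the internal prediction, evaluated at the
#' observed step velocities.
#'
#' Two conventions are available for the step-velocity gradients. The
#' `"analytic"` convention is the chain-rule derivative of
#' `0.5 * (p - SVA)^2` through `SVA = (f - s)/(f + s)`:
#' `de/df = (SVA - p) * 2 s/(f+s)^2` and `de/ds = -(SVA - p) * 2 f/(f+s)^2`.
#' The `"printed"` convention is the published closed form
#' `de/ds = -2 f ((s - f) + p (s + f)) / (s + f)^3` (and symmetrically with
#' `-2 s` for `de/df`); it equals the analytic form for the fast leg and its
#' negative for the slow leg, so the two conventions prescribe different
#' slow-leg threshold corrections. The prediction gradient
#' `de/dp = p - SVA` is convention-independent.
#'
#' @param sva_pred internal prediction.
#' @param sv_fast,sv_slow observed step velocities, m/s (sum must be
#'   non-zero).
#' @param convention `"analytic"` or `"printed"`.
#' @return named numeric vector `c(de_dsv_slow, de_dsv_fast, de_dsva_pred)`.
#' @export
error_gradients <- function(sva_pred, sv_fast, sv_slow,
                            convention = c("analytic", "printed")) {
  convention <- match.arg(convention)
  den <- sv_fast + sv_slow
  if (den == 0) stop("sv_fast + sv_slow must be non-zero")
  sva <- (sv_fast - sv_slow) / den
  de_dp <- sva_pred - sva
  if (convention == "analytic") {
    # d(SVA)/df = 2s/(f+s)^2 ; d(SVA)/ds = -2f/(f+s)^2 ; de/dSVA = -(p - SVA)
    de_df <- (sva - sva_pred) * 2 * sv_slow / den^2
    de_ds <- -(sva - sva_pred) * 2 * sv_fast / den^2
  } else {
    core <- (sv_slow - sv_fast) + sva_pred * den
    de_ds <- -2 * sv_fast * core / den^3
    de_df <- -2 * sv_slow * core / den^3
  }
  c(de_dsv_slow = de_ds, de_dsv_fast = de_df, de_dsva_pred = de_dp)
}

#' Update the internal prediction
#'
#' One gradient-descent step of the internal SVA prediction toward the
#' observed SVA: `p' = p - alpha * (p - sva)`. With `0 < alpha < 1` the gap
#' to the observation contracts by the factor `1 - alpha` per update.
#'
#' @param state a [cerebellar_state()].
#' @param sva observed step velocity asymmetry.
#' @return updated state.
#' @export
update_prediction <- function(state, sva) {
  stopifnot(inherits(state, "cerebellar_state"))
  state$sva_pred <- state$sva_pred - state$alpha * (state$sva_pred - sva)
  state
}

#' Update the swing-initiation thresholds
#'
#' Moves each leg's swing-initiation threshold along the negative of its
#' step-velocity error gradient, scaled by the shared adaptation rate
#' `beta` and the signed sensitivity factor, then clips to the configured
#' bounds: `t_leg' = clip(t_leg - beta * sens_leg * de/dsv_leg)`.
#'
#' @param state a [cerebellar_state()].
#' @param obs a [step_observation()].
#' @return updated state.
#' @export
update_thresholds <- function(state, obs) {
  stopifnot(inherits(state, "cerebellar_state"),
            inherits(obs, "step_observation"))
  g <- error_gradients(state$sva_pred, obs$sv_fast, obs$sv_slow,
                       convention = state$convention)
  state$t_fast <- state$t_fast -
    state$beta * state$sensitivity[["fast"]] * g[["de_dsv_fast"]]
  state$t_slow <- state$t_slow -
    state$beta * state$sensitivity[["slow"]] * g[["de_dsv_slow"]]
  state$t_fast <- min(max(state$t_fast, state$t_bounds[1]), state$t_bounds[2])
  state$t_slow <- min(max(state$t_slow, state$t_bounds[1]), state$t_bounds[2])
  state
}

#' One step observation (both legs' most recent steps)
#'
#' @param l_fast,l_slow step lengths, meters.
#' @param d_fast,d_slow step times, seconds (> 0).
#' @return `step_observation` with the derived step velocities.
#' @export
step_observation <- function(l_fast, l_slow, d_fast, d_slow) {
  sv_fast <- step_velocity(l_fast, d_fast)
  sv_slow <- step_velocity(l_slow, d_slow)
  structure(list(l_fast = l_fast, l_slow = l_slow,
                 d_fast = d_fast, d_slow = d_slow,
                 sv_fast = sv_fast, sv_slow = sv_slow),
            class = "step_observation")
}

#' Cerebellar update at a heel strike
#'
#' Called shortly after every heel strike. From the stride buffer (the most
#' recent step length and step time of each leg) it computes the observed
#' SVA, evaluates the prediction error and its gradients at the pre-update
#' prediction, and then applies the threshold and prediction updates
#' simultaneously, both from that same pre-update state. An incomplete
#' buffer (warm-up: one of the legs has not yet completed a step) is a
#' no-op flagged in the diagnostics.
#'
#' @param state a [cerebellar_state()].
#' @param stride_buffer a [step_observation()], or `NULL`/incomplete during
#'   warm-up.
#' @return list with elements `state` (updated) and `diagnostics` (named
#'   list: `warm_up`, `sva`, `sva_pred_pre`, `error`, gradients, updated
#'   thresholds, `convention`).
#' @export
on_heel_strike <- function(state, stride_buffer) {
  stopifnot(inherits(state, "cerebellar_state"))
  incomplete <- is.null(stride_buffer) ||
    !inherits(stride_buffer, "step_observation") ||
    !all(is.finite(unlist(stride_buffer)))
  if (incomplete) {
    return(list(state = state,
                diagnostics = list(warm_up = TRUE, convention = state$convention)))
  }
  obs <- stride_buffer
  sva <- step_velocity_asymmetry(obs$sv_fast, obs$sv_slow)
  g <- error_gradients(state$sva_pred, obs$sv_fast, obs$sv_slow,
                       convention = state$convention)
  err <- prediction_error(state$sva_pred, sva)
  pre <- state
  state <- update_thresholds(pre, obs)
  state$sva_pred <- update_prediction(pre, sva)$sva_pred
  diag <- list(warm_up = FALSE, sva = sva, sva_pred_pre = pre$sva_pred,
               sva_pred = state$sva_pred, error = err,
               de_dsv_slow = g[["de_dsv_slow"]],
               de_dsv_fast = g[["de_dsv_fast"]],
               de_dsva_pred = g[["de_dsva_pred"]],
               t_fast = state$t_fast, t_slow = state$t_slow,
               convention = state$convention)
  list(state = state, diagnostics = diag)
}
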