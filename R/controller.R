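#' Spinal reflex controller
#'
#' Phase-gated reflex layer: a five-phase state machine per leg (early
#' stance ES, mid-stance MS, pre-swing PS, swing SW, landing preparation
#' LP), delayed sensory channels (5--20 ms neural delays), and a set of
#' control laws -- muscle force feedback (F), muscle length feedback (L),
#' constant feedforward signals (C), and pelvis-tilt PD control -- that map
#' delayed sensory samples to muscle excitations. The MS->PS transition is
#' the timed swing-initiation trigger: it fires when the time since the
#' leg's own heel strike exceeds the threshold `t`, the single spinal
#' parameter the cerebellar layer adapts.
#'
#' @name spinal_controller
NULL

#' Gait phases, in cycle order
#' @return character vector `c("ES","MS","PS","SW","LP")`.
#' @export
leg_phases <- function() c("ES", "MS", "PS", "SW", "LP")

#' Create a controller state
#'
#' @param t_fast,t_slow per-leg swing-initiation thresholds, seconds (when
#'   the cerebellum is enabled these are read from its state each stride).
#' @param phase_fast,phase_slow initial phases.
#' @param landing_prep_angle limb angle (radians forward of vertical) at
#'   which a swinging leg switches to landing preparation.
#' @return object of class `controller_state`.
#' @export
controller_state <- function(t_fast = 0.35, t_slow = 0.35,
                             phase_fast = "ES", phase_slow = "SW",
                             landing_prep_angle = 0.1) {
  stopifnot(phase_fast %in% leg_phases(), phase_slow %in% leg_phases())
  structure(list(
    phase = c(fast = phase_fast, slow = phase_slow),
    t_since_hs = c(fast = 0, slow = 0),
    threshold = c(fast = t_fast, slow = t_slow),
    landing_prep_angle = landing_prep_angle,
    last_time = NA_real_
  ), class = "controller_state")
}

other_leg <- function(leg) if (leg == "fast") "slow" else "fast"

#' Advance one leg's gait phase from a sensory sample
#'
#' Applies at most one transition per sample, following the cycle
#' ES -> MS -> PS -> SW -> LP -> ES:
#' \itemize{
#'   \item ES -> MS when the contralateral foot leaves the ground;
#'   \item MS -> PS at the first sample whose time since the ipsilateral
#'     heel strike reaches the swing-initiation threshold `t` (the timed
#'     trigger replacing the classical contralateral-heel-strike trigger);
#'   \item PS -> SW when the ipsilateral contact flag drops;
#'   \item SW -> LP when the swinging limb angle passes the landing
#'     preparation angle;
#'   \item LP -> ES at ipsilateral contact (heel strike; resets the
#'     ipsilateral timer).
#' }
#'
#' @param state a [controller_state()].
#' @param sensory list with `time` (s), `contact` (named logical,
#'   fast/slow), `limb_angle` (named numeric, radians).
#' @param leg `"fast"` or `"slow"`.
#' @return updated state.
#' @export
advance_phase <- function(state, sensory, leg = c("fast", "slow")) {
  leg <- match.arg(leg)
  stopifnot(inherits(state, "controller_state"))
  dt <- if (is.na(state$last_time)) 0 else sensory$time - state$last_time
  if (dt < 0) stop("sensory sample times must be non-decreasing")
  state$t_since_hs[leg] <- state$t_since_hs[leg] + dt
  state$last_time <- sensory$time

  ph <- state$phase[[leg]]
  contra <- other_leg(leg)
  ipsi_contact <- isTRUE(sensory$contact[[leg]])
  contra_contact <- isTRUE(sensory$contact[[contra]])
  angle <- sensory$limb_angle[[leg]]

  new <- ph
  if (ph == "ES" && !contra_contact) {
    new <- "MS"
  } else if (ph == "MS" && state$t_since_hs[[leg]] >= state$threshold[[leg]]) {
    new <- "PS"
  } else if (ph == "PS" && !ipsi_contact) {
    new <- "SW"
  } else if (ph == "SW" && !is.null(angle) && is.finite(angle) &&
             angle >= state$landing_prep_angle) {
    new <- "LP"
  } else if (ph == "LP" && ipsi_contact) {
    new <- "ES"
    state$t_since_hs[leg] <- 0  # heel strike resets the ipsilateral timer
  }
  state$phase[leg] <- new
  state
}

parse_phases <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]

#' Muscle excitations from the phase-gated control laws
#'
#' Sums the outputs of all laws active in the leg's current phase and clips
#' to `[baseline, 1]` (baseline 0.01). Law outputs: F law
#' `sign * gain * delayed normalized force of the source muscle`; L law
#' `sign * gain * max(0, delayed normalized length of source - offset)`;
#' C law a constant; PD law
#' `sign * (kp * (tilt - theta_ref) + kd * tilt_velocity)`.
#'
#' @param state a [controller_state()].
#' @param delayed_sensory list with named numeric vectors `force` and
#'   `length` (normalized, per muscle), scalars `tilt` (rad) and
#'   `tilt_velocity` (rad/s). The caller applies the neural delays, e.g.
#'   via [delayed_series()].
#' @param laws reflex data frame for ONE leg (rows of the `reflex` element
#'   of [default_controller_config()] for that side: columns law, target,
#'   kind, sign, source, phases, param, value).
#' @param leg `"fast"` or `"slow"`.
#' @param baseline minimum excitation.
#' @return named numeric vector of excitations over the seven muscle
#'   groups, each in `[baseline, 1]`.
#' @export
muscle_excitations <- function(state, delayed_sensory, laws,
                               leg = c("fast", "slow"), baseline = 0.01) {
  leg <- match.arg(leg)
  stopifnot(inherits(state, "controller_state"))
  phase <- state$phase[[leg]]
  exc <- stats::setNames(rep(baseline, length(MUSCLE_GROUPS)), MUSCLE_GROUPS)
  if (nrow(laws) == 0L) return(exc)
  bad <- setdiff(unique(laws$target), MUSCLE_GROUPS)
  if (length(bad)) stop(sprintf("unknown muscle name: %s", bad[1]))

  for (id in unique(laws$law)) {
    rows <- laws[laws$law == id, , drop = FALSE]
    if (!(phase %in% parse_phases(rows$phases[1]))) next
    p <- stats::setNames(rows$value, rows$param)
    kind <- rows$kind[1]
    sgn <- rows$sign[1]
    target <- rows$target[1]
    out <- switch(kind,
      F = {
        src <- rows$source[1]
        if (!src %in% names(delayed_sensory$force)) {
          stop(sprintf("unknown muscle name: %s", src))
        }
        sgn * p[["gain"]] * delayed_sensory$force[[src]]
      },
      L = {
        src <- rows$source[1]
        if (!src %in% names(delayed_sensory$length)) {
          stop(sprintf("unknown muscle name: %s", src))
        }
        off <- if ("offset" %in% names(p)) p[["offset"]] else 0
        sgn * p[["gain"]] * max(0, delayed_sensory$length[[src]] - off)
      },
      C = sgn * p[["constant"]],
      PD = {
        ref <- if ("theta_ref" %in% names(p)) p[["theta_ref"]] else 0
        sgn * (p[["kp"]] * (delayed_sensory$tilt - ref) +
                 p[["kd"]] * delayed_sensory$tilt_velocity)
      },
      stop(sprintf("unknown law kind: %s", kind)))
    exc[target] <- exc[target] + out
  }
  pmin(pmax(exc, baseline), 1)
}

#' Apply a neural transmission delay to a sampled signal
#'
#' Returns the signal shifted by `delay`: the output at time `tau` is the
#' input at `tau - delay` (zero-order hold between samples). Queries before
#' the first sample plus the delay return the held first value.
#'
#' @param times sample times, seconds, strictly increasing.
#' @param values signal samples (numeric vector, same length).
#' @param delay transmission delay, seconds, >= 0 (5--20 ms for the spinal
#'   channels, by nerve path length).
#' @param xout query times; defaults to `times` (a uniformly re-timed copy
#'   of the stream).
#' @return numeric vector of delayed samples at `xout`.
#' @export
delayed_series <- function(times, values, delay, xout = times) {
  if (length(delay) != 1L || !is.finite(delay) || delay < 0) {
    stop("delay must be a single non-negative number")
  }
  stopifnot(length(times) == length(values), length(times) >= 1L)
  if (length(times) == 1L) return(rep(values, length(xout)))
  # the 1 ns guard breaks floating-point ties toward the knot itself, so a
  # sample delayed by an exact multiple of the period lands on its knot
  stats::approx(times, values, xout = xout - delay + 1e-9,
                method = "constant", f = 0, rule = 2)$y
}
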