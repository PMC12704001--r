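#' Tiered treadmill objective
#'
#' Cost function for treadmill walking. The gate term penalizes
#' simulations that end before the requested duration (fall or drift);
#' only once the full duration is achieved are the secondary terms --
#' effort (metabolic rate + cubed activations), upper-body motion, joint
#' limits, and station keeping -- evaluated and summed.
#'
#' @name objective
NULL

#' Objective weights
#'
#' Defaults are the shipped weight factors of the individual terms.
#'
#' @param w_ub upper-body penalty weight.
#' @param w_pos station-keeping weight.
#' @param w_met metabolic-rate weight.
#' @param w_act cubed-activation weight.
#' @param w_ankle ankle range-penalty weight.
#' @param w_knee knee limit-torque weight.
#' @return named list of non-negative weights.
#' @export
objective_weights <- function(w_ub = 0.05, w_pos = 100, w_met = 0.001,
                              w_act = 20, w_ankle = 0.1, w_knee = 0.01) {
  w <- list(w_ub = w_ub, w_pos = w_pos, w_met = w_met,
            w_act = w_act, w_ankle = w_ankle, w_knee = w_knee)
  stopifnot(all(unlist(w) >= 0))
  w
}

trapz <- function(t, y) {
  if (length(t) < 2L) return(0)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Assemble a trajectory record
#'
#' Container for the simulated signals the objective integrates.
#'
#' @param time sample times, s, non-decreasing.
#' @param com_height vertical COM height, m.
#' @param pelvis_x anterior pelvis COM position, m.
#' @param tilt_velocity pelvis tilt velocity, deg/s.
#' @param activations matrix (samples x muscles) of activations in [0, 1].
#' @param met_rate metabolic rate, W (scalar mean or per-sample vector);
#'   comes from a pluggable energy model, see [proxy_metabolic_rate()].
#' @param ankle_left,ankle_right ankle angles, degrees.
#' @param knee_torque_left,knee_torque_right knee limit torques, N m
#'   (default zero: the surrogate has no knee-ligament model).
#' @param hs_times named list of heel-strike time vectors per leg.
#' @param tend achieved duration, s; `tdes` requested duration, s.
#' @param tdes requested duration, s.
#' @return object of class `trajectory_record`.
#' @export
trajectory_record <- function(time, com_height, pelvis_x, tilt_velocity,
                              activations, met_rate = 0,
                              ankle_left = NULL, ankle_right = NULL,
                              knee_torque_left = NULL, knee_torque_right = NULL,
                              hs_times = list(), tend = max(time), tdes = tend) {
  n <- length(time)
  zero <- rep(0, n)
  if (is.null(ankle_left)) ankle_left <- zero
  if (is.null(ankle_right)) ankle_right <- zero
  if (is.null(knee_torque_left)) knee_torque_left <- zero
  if (is.null(knee_torque_right)) knee_torque_right <- zero
  activations <- as.matrix(activations)
  stopifnot(!is.unsorted(time), nrow(activations) == n,
            all(activations >= 0 & activations <= 1))
  structure(list(time = time, com_height = com_height, pelvis_x = pelvis_x,
                 tilt_velocity = tilt_velocity, activations = activations,
                 met_rate = met_rate,
                 ankle_left = ankle_left, ankle_right = ankle_right,
                 knee_torque_left = knee_torque_left,
                 knee_torque_right = knee_torque_right,
                 hs_times = hs_times, tend = tend, tdes = tdes),
            class = "trajectory_record")
}

#' Early-stopping check
#'
#' A simulation stops early when the vertical COM drops below 85% of its
#' initial height (fall) or the anterior pelvis COM deviates more than
#' 10 m from its initial position (drift).
#'
#' @param sample list with `com_height` and `pelvis_x`.
#' @param initial list with the initial `com_height` and `pelvis_x`.
#' @return list `(stop = logical, reason = "fall"/"drift"/NA)`.
#' @export
early_stop_check <- function(sample, initial) {
  if (sample$com_height < 0.85 * initial$com_height) {
    return(list(stop = TRUE, reason = "fall"))
  }
  if (abs(sample$pelvis_x - initial$pelvis_x) > 10) {
    return(list(stop = TRUE, reason = "drift"))
  }
  list(stop = FALSE, reason = NA_character_)
}

#' Gate term
#'
#' Zero when the achieved duration equals the requested one; otherwise
#' `500000 / tend`, so earlier failures cost more.
#'
#' @param tend achieved duration, s (> 0, <= `tdes`).
#' @param tdes requested duration, s.
#' @return gate cost.
#' @export
j_t <- function(tend, tdes) {
  if (!is.finite(tend) || tend <= 0) stop("tend must be positive")
  stopifnot(tend <= tdes)
  if (tend == tdes) 0 else 500000 / tend
}

#' Effort term
#'
#' `w_met * mean metabolic rate + w_act * (1/M) * integral of the summed
#' cubed activations` (trapezoidal integration over the record).
#'
#' @param record a [trajectory_record()].
#' @param weights an [objective_weights()].
#' @return effort cost.
#' @export
j_eff <- function(record, weights = objective_weights()) {
  M <- ncol(record$activations)
  act_int <- trapz(record$time, rowSums(record$activations^3))
  weights$w_met * mean(record$met_rate) + weights$w_act * act_int / M
}

#' Upper-body term
#'
#' A penalty rate of 100 accrues whenever the absolute pelvis tilt
#' velocity exceeds 10 deg/s (strict inequality), integrated over the
#' violation time and scaled by `w_ub`.
#'
#' @inheritParams j_eff
#' @return upper-body cost.
#' @export
j_ub <- function(record, weights = objective_weights()) {
  viol <- as.numeric(abs(record$tilt_velocity) > 10)
  weights$w_ub * 100 * trapz(record$time, viol)
}

ankle_penalty <- function(alpha, range) {
  ifelse(alpha < range[1], range[1] - alpha,
         ifelse(alpha > range[2], alpha - range[2], 0))
}

#' Joint-limit term
#'
#' Squared ankle range-of-motion excess (outside `ankle_range`, degrees)
#' integrated for both sides and weighted by `w_ankle`, plus the absolute
#' knee limit torques integrated and weighted by `w_knee`.
#'
#' @inheritParams j_eff
#' @param ankle_range admissible ankle range, degrees.
#' @return joint-limit cost.
#' @export
j_dofs <- function(record, weights = objective_weights(),
                   ankle_range = c(-60, 60)) {
  pl <- ankle_penalty(record$ankle_left, ankle_range)
  pr <- ankle_penalty(record$ankle_right, ankle_range)
  ankle <- weights$w_ankle * trapz(record$time, pl^2 + pr^2)
  knee <- weights$w_knee * trapz(record$time, abs(record$knee_torque_left) +
                                   abs(record$knee_torque_right))
  ankle + knee
}

#' Station-keeping term
#'
#' Weighted absolute drift of the anterior COM between the third and the
#' last heel strike of the reference leg (the third is used so the model
#' can settle first). The absolute value makes the penalty
#' sign-independent.
#'
#' @inheritParams j_eff
#' @param leg reference leg name in `record$hs_times`.
#' @return station-keeping cost.
#' @export
j_pos <- function(record, weights = objective_weights(), leg = NULL) {
  if (is.null(leg)) leg <- names(record$hs_times)[1]
  hs <- record$hs_times[[leg]]
  if (is.null(hs) || length(hs) < 3L) {
    stop("j_pos needs at least 3 heel strikes of the reference leg")
  }
  comx <- stats::approx(record$time, record$pelvis_x,
                        xout = c(hs[3], hs[length(hs)]), rule = 2)$y
  weights$w_pos * abs(comx[1] - comx[2])
}

#' Evaluate the tiered objective
#'
#' Returns the gate term alone whenever it is positive (the simulation
#' ended early); otherwise the sum of the effort, upper-body, joint-limit,
#' and station-keeping terms. The per-term breakdown is always reported.
#'
#' @inheritParams j_eff
#' @param ankle_range admissible ankle range, degrees.
#' @return list with `total`, `gated` (logical), and `terms` (named list
#'   j_t, j_eff, j_ub, j_dofs, j_pos).
#' @export
evaluate_objective <- function(record, weights = objective_weights(),
                               ankle_range = c(-60, 60)) {
  jt <- j_t(record$tend, record$tdes)
  terms <- list(
    j_t = jt,
    j_eff = j_eff(record, weights),
    j_ub = j_ub(record, weights),
    j_dofs = j_dofs(record, weights, ankle_range),
    j_pos = tryCatch(j_pos(record, weights), error = function(e) NA_real_)
  )
  if (jt > 0) {
    list(total = jt, gated = TRUE, terms = terms)
  } else {
    secondary <- terms$j_eff + terms$j_ub + terms$j_dofs +
      (if (is.na(terms$j_pos)) 0 else terms$j_pos)
    list(total = secondary, gated = FALSE, terms = terms)
  }
}

#' Proxy metabolic rate (NOT a published energy model)
#'
#' Pluggable stand-in used where a metabolic rate is needed: the
#' activation-weighted sum `sum_i w_i * a_i^2` per sample. It is a
#' placeholder proxy, not the muscle-energetics model used with the full
#' dynamics.
#'
#' @param activations matrix (samples x muscles).
#' @param muscle_weights per-muscle weight factors (default 1).
#' @return per-sample proxy rate, W.
#' @export
proxy_metabolic_rate <- function(activations, muscle_weights = NULL) {
  activations <- as.matrix(activations)
  if (is.null(muscle_weights)) muscle_weights <- rep(1, ncol(activations))
  as.numeric(activations^2 %*% muscle_weights)
}
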