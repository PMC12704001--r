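#' Reduced-order split-belt walker (surrogate plant)
#'
#' Event-driven stand-in for the full muscle-driven forward dynamics. It
#' preserves exactly the causal chain the cerebellar layer exploits: the
#' swing-initiation threshold sets how long a leg stays in stance, the
#' stance foot is carried backward by its belt, and foot placement at heel
#' strike fixes the step length and step time, hence the step velocities
#' and their asymmetry. Each leg lifts off `t_leg + d_PS` after its own
#' heel strike and lands `d_SW` later at its anterior placement offset, so
#' a leg's cycle duration is `t_leg + d_PS + d_SW` and the two heel-strike
#' trains interleave. This is a surrogate for desk-scale testing, not a
#' replication of the 9-DOF musculoskeletal simulation.
#'
#' @name surrogate_plant
NULL

#' Plant parameters
#'
#' @param v_fast,v_slow belt speeds, m/s (`v_fast >= v_slow > 0`); the
#'   split-belt protocol runs 1.0 vs 0.5 m/s.
#' @param a_fast,a_slow anterior foot-placement offsets at heel strike,
#'   meters in the pelvis frame. The defaults differ by 0.06 m so that the
#'   open-loop split-belt asymmetry sits near the early-adaptation operating
#'   point (SLA about -0.16).
#' @param d_PS pre-swing duration, s (liftoff occurs `t + d_PS` after the
#'   leg's own heel strike).
#' @param d_SW swing duration, s.
#' @param pelvis_height pelvis height, m, for limb-angle synthesis.
#' @param noise_sd additive Gaussian placement noise, m (0 for tests,
#'   0.005 for demos).
#' @param min_step_time smallest admissible step time, s; shorter steps
#'   raise a plant-degenerate error.
#' @param phase_gain entrainment gain in (0, 1]: the fraction by which the
#'   slow (reference) leg's landing phase-locks to the fast leg's
#'   heel-strike train each stride. The fast-leg cycle stays rigid at
#'   `t_fast + d_PS + d_SW`, so the conservation law
#'   `d_fast + d_slow = t_fast + d_PS + d_SW` holds exactly; without this
#'   coupling the inter-leg phase integrates any threshold difference and
#'   the walker degenerates within tens of strides (see the methods
#'   vignette). The correction vanishes on any path with equal thresholds.
#' @param dt sample period for synthesized waveforms, s.
#' @return object of class `plant_parameters`.
#' @export
plant_parameters <- function(v_fast = 1.0, v_slow = 0.5,
                             a_fast = 0.33, a_slow = 0.27,
                             d_PS = 0.15, d_SW = 0.40,
                             pelvis_height = 0.9,
                             noise_sd = 0, min_step_time = 0.1,
                             phase_gain = 0.5,
                             dt = 0.001) {
  stopifnot(v_fast >= v_slow, v_slow > 0, d_PS > 0, d_SW > 0,
            pelvis_height > 0, noise_sd >= 0, min_step_time > 0, dt > 0,
            phase_gain >= 0, phase_gain <= 1)
  structure(list(v_fast = v_fast, v_slow = v_slow,
                 a_fast = a_fast, a_slow = a_slow,
                 d_PS = d_PS, d_SW = d_SW,
                 pelvis_height = pelvis_height,
                 noise_sd = noise_sd, min_step_time = min_step_time,
                 phase_gain = phase_gain,
                 dt = dt),
            class = "plant_parameters")
}

#' Symmetric (tied-belt) plant parameters
#'
#' Equal belt speeds, equal placement offsets, for baseline fixtures.
#'
#' @param v belt speed for both belts, m/s.
#' @param a placement offset for both legs, m.
#' @param ... passed to [plant_parameters()].
#' @export
symmetric_plant_parameters <- function(v = 1.0, a = 0.30, ...) {
  plant_parameters(v_fast = v, v_slow = v, a_fast = a, a_slow = a, ...)
}

#' Initialize the plant event state
#'
#' Places the virtual previous fast heel strike half a fast cycle before
#' time zero, so that with equal thresholds the walker starts at the
#' alternating steady state of the map.
#'
#' @param plant a [plant_parameters()].
#' @param t_fast,t_slow thresholds in effect at start, s.
#' @return plant state list (event bookkeeping).
#' @export
init_plant_state <- function(plant, t_fast, t_slow) {
  c_fast <- t_fast + plant$d_PS + plant$d_SW
  hs_fast <- -c_fast / 2
  to_fast <- hs_fast + t_fast + plant$d_PS
  list(stride = 0L,
       last_fast_hs = hs_fast,
       a_fast_prev = plant$a_fast,
       to_fast_pending = to_fast,
       x_to_fast_pending = plant$a_fast - plant$v_fast * (t_fast + plant$d_PS),
       next_fast_hs = to_fast + plant$d_SW,
       next_slow_hs = 0)
}

#' Advance the walker by one stride
#'
#' One stride = the slow-leg heel strike followed by the fast-leg heel
#' strike. Step time is measured from the contralateral heel strike; step
#' length at a heel strike is the striking foot's placement minus the
#' contralateral stance foot's position (which has been carried backward by
#' its belt since its own heel strike). The thresholds passed in are those
#' in effect for this stride; they schedule each leg's next liftoff and
#' heel strike (`hs + t_leg + d_PS + d_SW`).
#'
#' @param plant a [plant_parameters()].
#' @param state plant state from [init_plant_state()] or a previous call.
#' @param t_fast,t_slow swing-initiation thresholds, s.
#' @return list with `record` (one-row data frame stride record) and
#'   `state` (advanced). Raises a plant-degenerate error naming the stride
#'   if a step time falls below `min_step_time`.
#' @export
next_stride <- function(plant, state, t_fast, t_slow) {
  k <- state$stride + 1L
  noise <- function() if (plant$noise_sd > 0) stats::rnorm(1, 0, plant$noise_sd) else 0

  # --- slow-leg heel strike ---
  hs_slow <- state$next_slow_hs
  d_slow <- hs_slow - state$last_fast_hs
  if (!is.finite(d_slow) || d_slow <= plant$min_step_time) {
    stop(sprintf("plant degenerate at stride %d: slow step time %.4f s <= %.3f s",
                 k, d_slow, plant$min_step_time))
  }
  a_slow_k <- plant$a_slow + noise()
  x_fast_stance <- state$a_fast_prev - plant$v_fast * d_slow
  l_slow <- a_slow_k - x_fast_stance
  to_slow <- hs_slow + t_slow + plant$d_PS
  x_to_slow <- a_slow_k - plant$v_slow * (t_slow + plant$d_PS)

  # --- fast-leg heel strike ---
  hs_fast <- state$next_fast_hs
  d_fast <- hs_fast - hs_slow
  if (!is.finite(d_fast) || d_fast <= plant$min_step_time) {
    stop(sprintf("plant degenerate at stride %d: fast step time %.4f s <= %.3f s",
                 k, d_fast, plant$min_step_time))
  }
  a_fast_k <- plant$a_fast + noise()
  x_slow_stance <- a_slow_k - plant$v_slow * d_fast
  l_fast <- a_fast_k - x_slow_stance
  to_fast <- hs_fast + t_fast + plant$d_PS
  x_to_fast <- a_fast_k - plant$v_fast * (t_fast + plant$d_PS)
  next_fast_hs <- to_fast + plant$d_SW

  # slow-leg landing phase-locks to the fast heel-strike train; exact
  # nominal landing (to_slow + d_SW) whenever the thresholds are equal
  c_fast_cur <- t_fast + plant$d_PS + plant$d_SW
  next_slow_hs <- (1 - plant$phase_gain) * (to_slow + plant$d_SW) +
    plant$phase_gain * (hs_fast + c_fast_cur / 2)

  record <- data.frame(
    stride = k,
    hs_slow = hs_slow, a_slow = a_slow_k, d_slow = d_slow, l_slow = l_slow,
    sv_slow = l_slow / d_slow,
    hs_fast = hs_fast, a_fast = a_fast_k, d_fast = d_fast, l_fast = l_fast,
    sv_fast = l_fast / d_fast,
    hs_fast_prev = state$last_fast_hs, a_fast_prev = state$a_fast_prev,
    to_fast_prev = state$to_fast_pending,
    x_to_fast_prev = state$x_to_fast_pending,
    to_slow = to_slow, x_to_slow = x_to_slow,
    to_fast = to_fast, x_to_fast = x_to_fast,
    hs_slow_next = next_slow_hs,
    t_fast = t_fast, t_slow = t_slow,
    sla = (l_fast - l_slow) / (l_fast + l_slow),
    sva = (l_fast / d_fast - l_slow / d_slow) /
      (l_fast / d_fast + l_slow / d_slow),
    sva_pred = NA_real_, error = NA_real_
  )
  state$stride <- k
  state$last_fast_hs <- hs_fast
  state$a_fast_prev <- a_fast_k
  state$to_fast_pending <- to_fast
  state$x_to_fast_pending <- x_to_fast
  state$next_fast_hs <- next_fast_hs
  state$next_slow_hs <- next_slow_hs
  list(record = record, state = state)
}

limb_angle <- function(x, pelvis_height) atan2(x, pelvis_height)

# Piecewise limb-angle trace of one leg over query times: stance follows the
# belt-carried foot; swing is a smooth half-cosine from trailing to
# placement angle.
leg_angle_trace <- function(tt, hs1, a1, to1, x_to1, hs2, a2, v, h) {
  th_to <- limb_angle(x_to1, h)
  th_land <- limb_angle(a2, h)
  ang <- numeric(length(tt))
  stance <- tt >= hs1 & tt < to1
  swing <- tt >= to1 & tt < hs2
  after <- tt >= hs2
  ang[stance] <- limb_angle(a1 - v * (tt[stance] - hs1), h)
  if (any(swing)) {
    u <- (tt[swing] - to1) / (hs2 - to1)
    ang[swing] <- th_to + (th_land - th_to) * (1 - cos(pi * u)) / 2
  }
  ang[after] <- limb_angle(a2 - v * (tt[after] - hs2), h)
  before <- tt < hs1
  ang[before] <- NA_real_
  ang
}

#' Limb-angle waveforms for one stride
#'
#' Synthesizes the limb angle (angle between the vertical and the
#' pelvis-to-foot vector, radians, positive forward) of both legs over one
#' stride window (slow heel strike to the next slow heel strike), sampled
#' at the plant's `dt`. Stance-phase angles follow the belt-carried foot,
#' `atan(x_foot / pelvis_height)`; swing interpolates smoothly (half
#' cosine) from the trailing liftoff angle to the landing angle. The
#' upcoming placements use the nominal offsets (exact when `noise_sd = 0`).
#'
#' @param record one stride record from [next_stride()].
#' @param plant the [plant_parameters()] that produced it.
#' @return data frame with columns `time`, `theta_fast`, `theta_slow`
#'   (radians).
#' @export
limb_angle_waveform <- function(record, plant) {
  r <- as.list(record[1, ])
  t0 <- r$hs_slow
  t1 <- r$hs_slow_next
  n <- max(2L, round((t1 - t0) / plant$dt))
  tt <- t0 + (seq_len(n) - 1L) * plant$dt
  h <- plant$pelvis_height
  theta_slow <- leg_angle_trace(tt, r$hs_slow, r$a_slow, r$to_slow,
                                r$x_to_slow, r$hs_slow_next, plant$a_slow,
                                plant$v_slow, h)
  # fast leg: in stance since its previous heel strike at window start
  theta_fast <- leg_angle_trace(tt, r$hs_fast_prev, r$a_fast_prev,
                                r$to_fast_prev, r$x_to_fast_prev,
                                r$hs_fast, r$a_fast, plant$v_fast, h)
  # beyond the fast heel strike the leg is in stance again
  post <- tt >= r$hs_fast
  theta_fast[post] <- limb_angle(r$a_fast - plant$v_fast * (tt[post] - r$hs_fast), h)
  data.frame(time = tt, theta_fast = theta_fast, theta_slow = theta_slow)
}

#' Gait-event table from stride records
#'
#' Flattens stride records into the event series used by the analysis
#' layer: heel-strike and toe-off events with the event foot's anterior
#' position, the contralateral foot position, and the limb angle.
#'
#' @param records data frame of stride records ([next_stride()] rows).
#' @param plant the matching [plant_parameters()].
#' @return data frame (time-ordered) with columns `stride`, `time`, `leg`,
#'   `event`, `foot_pos`, `other_foot_pos`, `limb_angle`.
#' @export
gait_events <- function(records, plant) {
  h <- plant$pelvis_height
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    data.frame(
      stride = r$stride,
      time = c(r$hs_slow, r$to_slow, r$hs_fast, r$to_fast),
      leg = c("slow", "slow", "fast", "fast"),
      event = c("HS", "TO", "HS", "TO"),
      foot_pos = c(r$a_slow, r$x_to_slow, r$a_fast, r$x_to_fast),
      other_foot_pos = c(r$a_fast_prev - plant$v_fast * r$d_slow, NA,
                         r$a_slow - plant$v_slow * r$d_fast, NA),
      limb_angle = limb_angle(c(r$a_slow, r$x_to_slow, r$a_fast, r$x_to_fast), h),
      stringsAsFactors = FALSE
    )
  })
  ev <- do.call(rbind, rows)
  ev[order(ev$time), , drop = FALSE]
}

#' Run the closed loop: surrogate plant + cerebellar adaptation
#'
#' Alternates [next_stride()] with cerebellar heel-strike updates
#' ([on_heel_strike()] at the slow and then the fast heel strike of every
#' stride; the first slow heel strike is a warm-up no-op because the fast
#' leg has not completed a step yet). Thresholds adapted during stride `k`
#' take effect from stride `k + 1`. Deterministic for a fixed seed.
#'
#' @param plant a [plant_parameters()].
#' @param cereb a [cerebellar_state()]; use `alpha = 0, beta = 0` for the
#'   reflex-only (no-adaptation) analogue.
#' @param n_strides number of strides, >= 2.
#' @param seed integer RNG seed (placement noise).
#' @return list with `records` (stride-record data frame, with `sva_pred`
#'   and `error` filled from the fast-heel-strike diagnostics), `table`
#'   (long per-step stride table, see [write_stride_table()]), `trace`
#'   (per-heel-strike diagnostics data frame), `state` (final cerebellar
#'   state), `plant`.
#' @export
run_closed_loop <- function(plant, cereb = cerebellar_state(),
                            n_strides = 80, seed = 1L) {
  stopifnot(n_strides >= 2)
  set.seed(seed)
  ps <- init_plant_state(plant, cereb$t_fast, cereb$t_slow)
  records <- vector("list", n_strides)
  trace <- vector("list", 2L * n_strides)
  prev <- NULL
  for (k in seq_len(n_strides)) {
    out <- next_stride(plant, ps, cereb$t_fast, cereb$t_slow)
    ps <- out$state
    r <- out$record

    # slow HS: most recent fast step is from the previous stride
    obs_slow <- if (is.null(prev)) NULL else
      step_observation(prev$l_fast, r$l_slow, prev$d_fast, r$d_slow)
    up <- on_heel_strike(cereb, obs_slow)
    cereb <- up$state
    trace[[2L * k - 1L]] <- c(list(stride = k, side = "slow",
                                   hs_time = r$hs_slow), up$diagnostics)

    # fast HS: both steps of this stride are complete
    obs_fast <- step_observation(r$l_fast, r$l_slow, r$d_fast, r$d_slow)
    up <- on_heel_strike(cereb, obs_fast)
    cereb <- up$state
    trace[[2L * k]] <- c(list(stride = k, side = "fast",
                              hs_time = r$hs_fast), up$diagnostics)

    r$sva_pred <- up$diagnostics$sva_pred_pre
    r$error <- up$diagnostics$error
    r$t_fast <- cereb$t_fast   # thresholds now in effect for stride k + 1
    r$t_slow <- cereb$t_slow
    records[[k]] <- r
    prev <- r
  }
  records <- do.call(rbind, records)
  trace_df <- do.call(rbind, lapply(trace, function(d) {
    data.frame(stride = d$stride, side = d$side, hs_time = d$hs_time,
               warm_up = isTRUE(d$warm_up),
               sva = d$sva %||% NA_real_,
               sva_pred = d$sva_pred %||% NA_real_,
               error = d$error %||% NA_real_,
               de_dsv_slow = d$de_dsv_slow %||% NA_real_,
               de_dsv_fast = d$de_dsv_fast %||% NA_real_,
               t_fast = d$t_fast %||% NA_real_,
               t_slow = d$t_slow %||% NA_real_,
               convention = d$convention,
               stringsAsFactors = FALSE)
  }))
  list(records = records, table = stride_table(records),
       trace = trace_df, state = cereb, plant = plant)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long per-step stride table
#'
#' One row per step (leg), in the exchange format of the analysis layer.
#'
#' @param records stride-record data frame.
#' @return data frame with columns `stride`, `side`, `hs_time`,
#'   `step_length_m`, `step_time_s`, `step_velocity_mps`, `t_fast_s`,
#'   `t_slow_s`, `sva`, `sva_pred`, `error`.
#' @export
stride_table <- function(records) {
  long <- rbind(
    data.frame(stride = records$stride, side = "slow",
               hs_time = records$hs_slow,
               step_length_m = records$l_slow, step_time_s = records$d_slow,
               step_velocity_mps = records$sv_slow,
               t_fast_s = records$t_fast, t_slow_s = records$t_slow,
               sva = records$sva, sva_pred = records$sva_pred,
               error = records$error, stringsAsFactors = FALSE),
    data.frame(stride = records$stride, side = "fast",
               hs_time = records$hs_fast,
               step_length_m = records$l_fast, step_time_s = records$d_fast,
               step_velocity_mps = records$sv_fast,
               t_fast_s = records$t_fast, t_slow_s = records$t_slow,
               sva = records$sva, sva_pred = records$sva_pred,
               error = records$error, stringsAsFactors = FALSE)
  )
  long[order(long$hs_time), , drop = FALSE]
}

#' Read/write stride tables as delimited text
#'
#' @param table a stride table ([stride_table()]).
#' @param path file path (tab-separated, with header).
#' @export
write_stride_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stride_table
#' @export
read_stride_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Synthetic fixtures
#'
#' Generates the datasets the analysis layer assumes: symmetric
#' (tied-belt) gait, asymmetric split-belt gait (both via the surrogate
#' plant, open loop with `alpha = beta = 0`), or a noisy exponential
#' series `y_s = a - b * exp(-s / c) + N(0, sd)` for fit-recovery studies.
#'
#' @param kind `"symmetric_gait"`, `"splitbelt_gait"`, or
#'   `"noisy_exponential_series"`.
#' @param params named list overriding defaults: for the gait kinds,
#'   `n_strides` plus [plant_parameters()] arguments; for the series,
#'   `a`, `b`, `c`, `sd`, `n`.
#' @param seed integer RNG seed.
#' @return for gait kinds, a list with `records`, `table`, `events`, and
#'   `plant`; for the exponential series, a data frame `(s, y)`.
#' @export
make_fixtures <- function(kind, params = list(), seed = 1L) {
  if (kind %in% c("symmetric_gait", "splitbelt_gait")) {
    n_strides <- params$n_strides %||% 20L
    params$n_strides <- NULL
    plant <- if (kind == "symmetric_gait") {
      do.call(symmetric_plant_parameters, params)
    } else {
      do.call(plant_parameters, params)
    }
    sim <- run_closed_loop(plant, cerebellar_state(alpha = 0, beta = 0),
                           n_strides = n_strides, seed = seed)
    list(records = sim$records, table = sim$table,
         events = gait_events(sim$records, plant), plant = plant)
  } else if (kind == "noisy_exponential_series") {
    a <- params$a %||% -0.03
    b <- params$b %||% -0.14
    cc <- params$c %||% 10
    sd <- params$sd %||% 0.01
    n <- params$n %||% 80L
    set.seed(seed)
    s <- seq_len(n)
    data.frame(s = s, y = a - b * exp(-s / cc) + stats::rnorm(n, 0, sd))
  } else {
    stop(sprintf("unknown fixture kind: %s", kind))
  }
}
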