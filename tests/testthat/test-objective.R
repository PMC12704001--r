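test_that("gate term is zero at full duration, 500000/tend otherwise", {
  expect_equal(j_t(80, 80), 0)
  expect_equal(j_t(50, 80), 10000)
  expect_equal(j_t(10, 80), 50000)
  expect_error(j_t(0, 80), "positive")
  expect_error(j_t(-5, 80), "positive")
})

test_that("early stopping triggers on falls and drift", {
  init <- list(com_height = 1.0, pelvis_x = 0)
  expect_equal(early_stop_check(list(com_height = 0.84, pelvis_x = 0), init),
               list(stop = TRUE, reason = "fall"))
  expect_equal(early_stop_check(list(com_height = 1.0, pelvis_x = 10.5), init),
               list(stop = TRUE, reason = "drift"))
  nominal <- early_stop_check(list(com_height = 0.98, pelvis_x = 0.3), init)
  expect_false(nominal$stop)
})

test_that("effort term integrates cubed activations and scales with metabolic rate", {
  w <- objective_weights()
  rec0 <- ideal_record(tend = 2)
  expect_equal(j_eff(rec0, w), 0)

  # single muscle at a = 0.5 for 2 s, w_act = 20, M = 1:
  # 20 * 0.5^3 * 2 = 5
  tt <- seq(0, 2, by = 0.01)
  rec <- trajectory_record(time = tt, com_height = rep(1, length(tt)),
                           pelvis_x = rep(0, length(tt)),
                           tilt_velocity = rep(0, length(tt)),
                           activations = matrix(0.5, length(tt), 1),
                           met_rate = 0, tend = 2)
  expect_equal(j_eff(rec, w), 5, tolerance = 1e-9)

  rec$met_rate <- 100
  base <- j_eff(rec, w)
  rec$met_rate <- 200
  expect_equal(j_eff(rec, w) - base, w$w_met * 100, tolerance = 1e-9)
})

test_that("upper-body term integrates the violation indicator at rate 100", {
  w <- objective_weights()
  tt <- seq(0, 2, by = 0.001)
  still <- trajectory_record(time = tt, com_height = rep(1, length(tt)),
                             pelvis_x = rep(0, length(tt)),
                             tilt_velocity = rep(0, length(tt)),
                             activations = matrix(0, length(tt), 1))
  expect_equal(j_ub(still, w), 0)

  # |tilt velocity| > 10 deg/s for exactly 1 s with w_ub = 0.05 -> 5
  viol <- still
  viol$tilt_velocity <- ifelse(tt >= 0.5 & tt < 1.5, 12, 0)
  expect_equal(j_ub(viol, w), 5, tolerance = 0.02)

  # exactly 10 deg/s is not a violation (strict inequality)
  edge <- still
  edge$tilt_velocity <- rep(10, length(tt))
  expect_equal(j_ub(edge, w), 0)
})

test_that("joint-limit term penalizes squared ankle excess and absolute knee torque", {
  w <- objective_weights()
  tt <- seq(0, 1, by = 0.001)
  n <- length(tt)
  mk <- function(ankle, knee = 0) {
    trajectory_record(time = tt, com_height = rep(1, n),
                      pelvis_x = rep(0, n), tilt_velocity = rep(0, n),
                      activations = matrix(0, n, 1),
                      ankle_left = rep(ankle, n),
                      knee_torque_left = rep(knee, n))
  }
  expect_equal(j_dofs(mk(30), w), 0)
  # ankle at 65 deg for 1 s: P = 5, term = 0.1 * 25 = 2.5
  expect_equal(j_dofs(mk(65), w), 2.5, tolerance = 1e-9)
  # continuity at the boundary: P -> 0 as the angle approaches the limit
  expect_lt(j_dofs(mk(60.001), w), 1e-6)
  # knee limit torque 3 N m for 1 s: 0.01 * 3
  expect_equal(j_dofs(mk(0, knee = 3), w), 0.03, tolerance = 1e-9)
})

test_that("station-keeping term uses the third and last reference heel strikes", {
  w <- objective_weights()
  rec <- ideal_record(tend = 10)
  expect_equal(j_pos(rec, w), 0)

  # linear drift: 0.02 m between HS3 and HSend -> 100 * 0.02 = 2
  hs <- rec$hs_times$slow
  drift_total <- 0.02 * rec$tend / (hs[length(hs)] - hs[3])
  rec$pelvis_x <- seq(0, drift_total, length.out = length(rec$time))
  expect_equal(j_pos(rec, w), 2, tolerance = 1e-6)

  rec$hs_times$slow <- hs[1:2]
  expect_error(j_pos(rec, w), "at least 3")
})

test_that("the objective is tiered: gate exclusively when positive, else the sum", {
  w <- objective_weights()
  # early-stopped record: total is the gate term alone
  rec <- ideal_record(tend = 50, tdes = 80)
  rec$tilt_velocity <- rep(20, length(rec$time))  # violations present
  ev <- evaluate_objective(rec, w)
  expect_true(ev$gated)
  expect_equal(ev$total, 10000)
  expect_gt(ev$terms$j_ub, 0)       # reported but excluded

  # ideal full-duration record costs zero
  ev0 <- evaluate_objective(ideal_record(tend = 10), w)
  expect_false(ev0$gated)
  expect_equal(ev0$total, 0)

  # full-duration record: total equals the sum of the secondary terms
  tt <- seq(0, 10, by = 0.01)
  n <- length(tt)
  rec2 <- trajectory_record(time = tt, com_height = rep(1, n),
                            pelvis_x = 0.001 * tt,
                            tilt_velocity = ifelse(tt < 2, 15, 0),
                            activations = matrix(0.3, n, 2),
                            met_rate = 50,
                            ankle_left = rep(61, n),
                            hs_times = list(slow = seq(0.5, 9.5, by = 0.9)))
  ev2 <- evaluate_objective(rec2, w)
  expect_false(ev2$gated)
  expect_equal(ev2$total,
               ev2$terms$j_eff + ev2$terms$j_ub + ev2$terms$j_dofs +
                 ev2$terms$j_pos, tolerance = 1e-12)
  expect_true(all(unlist(ev2$terms) >= 0))
})

test_that("each term scales linearly in its weight", {
  tt <- seq(0, 10, by = 0.01)
  n <- length(tt)
  rec <- trajectory_record(time = tt, com_height = rep(1, n),
                           pelvis_x = 0.001 * tt,
                           tilt_velocity = ifelse(tt < 2, 15, 0),
                           activations = matrix(0.3, n, 2),
                           met_rate = 0,
                           ankle_left = rep(61, n),
                           hs_times = list(slow = seq(0.5, 9.5, by = 0.9)))
  w <- objective_weights()
  w3 <- objective_weights(w_ub = 3 * w$w_ub)
  expect_equal(j_ub(rec, w3), 3 * j_ub(rec, w))
  w3 <- objective_weights(w_ankle = 3 * w$w_ankle)
  expect_equal(j_dofs(rec, w3), 3 * j_dofs(rec, w))
  w3 <- objective_weights(w_pos = 3 * w$w_pos)
  expect_equal(j_pos(rec, w3), 3 * j_pos(rec, w))
})

test_that("the proxy metabolic rate is a labeled activation-based stand-in", {
  a <- matrix(c(0.5, 0.2), 1, 2)
  expect_equal(proxy_metabolic_rate(a), 0.25 + 0.04)
  expect_equal(proxy_metabolic_rate(a, c(2, 1)), 0.5 + 0.04)
})
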