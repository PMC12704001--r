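test_that("step velocity is length over time, with a guarded denominator", {
  expect_equal(step_velocity(0.45, 0.5), 0.9)
  expect_equal(step_velocity(0, 0.5), 0)
  expect_error(step_velocity(0.5, 0), "positive")
})

test_that("step velocity asymmetry is the normalized difference", {
  expect_equal(step_velocity_asymmetry(1.0, 1.0), 0)
  expect_equal(step_velocity_asymmetry(1.2, 0.8), 0.2)
  # surrogate default steady state
  expect_equal(step_velocity_asymmetry(0.633, 0.867), -0.156, tolerance = 1e-3)
  expect_error(step_velocity_asymmetry(1, -1), "non-zero")
  # antisymmetry under swapping legs
  expect_equal(step_velocity_asymmetry(0.7, 1.1),
               -step_velocity_asymmetry(1.1, 0.7))
})

test_that("prediction error is half the squared prediction gap", {
  expect_equal(prediction_error(0, 0), 0)
  expect_equal(prediction_error(0.1, -0.1), 0.02)
  for (x in c(-0.3, 0, 0.42)) expect_equal(prediction_error(x, x), 0)
})

test_that("analytic gradients match a central finite-difference oracle", {
  set.seed(7)
  for (i in 1:100) {
    p <- stats::runif(1, -0.5, 0.5)
    f <- stats::runif(1, 0.2, 1.5)
    s <- stats::runif(1, 0.2, 1.5)
    g <- error_gradients(p, f, s, convention = "analytic")
    fd <- fd_error_gradients(p, f, s)
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("printed convention flips only the slow-leg gradient", {
  p <- 0.05; f <- 0.633; s <- 0.867
  ga <- error_gradients(p, f, s, convention = "analytic")
  gp <- error_gradients(p, f, s, convention = "printed")
  expect_equal(gp[["de_dsv_fast"]], ga[["de_dsv_fast"]], tolerance = 1e-12)
  expect_equal(gp[["de_dsv_slow"]], -ga[["de_dsv_slow"]], tolerance = 1e-12)
  expect_equal(gp[["de_dsva_pred"]], ga[["de_dsva_pred"]])
})

test_that("gradients vanish when the prediction matches the observation", {
  f <- 0.9; s <- 0.6
  sva <- step_velocity_asymmetry(f, s)
  for (conv in c("analytic", "printed")) {
    g <- error_gradients(sva, f, s, convention = conv)
    expect_equal(unname(g), c(0, 0, 0), tolerance = 1e-14)
  }
  expect_equal(unname(error_gradients(0, 1, 1)), c(0, 0, 0))
})

test_that("prediction update contracts toward the observation", {
  st <- cerebellar_state(alpha = 0.5)
  expect_equal(update_prediction(st, -0.2)$sva_pred, -0.1)
  expect_equal(update_prediction(cerebellar_state(alpha = 0), -0.2)$sva_pred, 0)
  expect_equal(update_prediction(cerebellar_state(alpha = 1), -0.2)$sva_pred, -0.2)

  # closed-form contraction: |gap_k| = (1 - alpha)^k |gap_0|
  alpha <- 0.13
  sva <- -0.156
  st <- cerebellar_state(alpha = alpha)
  gap0 <- abs(st$sva_pred - sva)
  for (k in 1:25) {
    st <- update_prediction(st, sva)
    expect_equal(abs(st$sva_pred - sva), (1 - alpha)^k * gap0)
  }
})

test_that("threshold updates follow -beta * gradient and are clipped", {
  # symmetric observation with zero prediction: nothing moves
  st <- cerebellar_state(alpha = 0.1, beta = 0.5)
  obs <- step_observation(0.45, 0.45, 0.45, 0.45)
  st2 <- update_thresholds(st, obs)
  expect_equal(st2$t_fast, st$t_fast)
  expect_equal(st2$t_slow, st$t_slow)

  # beta = 0: frozen even under asymmetry
  st0 <- cerebellar_state(beta = 0)
  obs_a <- step_observation(0.285, 0.39, 0.45, 0.45)
  st0b <- update_thresholds(st0, obs_a)
  expect_equal(st0b$t_fast, st0$t_fast)
  expect_equal(st0b$t_slow, st0$t_slow)

  # default surrogate steady state: change equals -beta * FD gradient
  beta <- 0.02
  st <- cerebellar_state(alpha = 0, beta = beta, convention = "analytic",
                         sensitivity = 1)
  obs <- step_observation(0.285, 0.39, 0.45, 0.45)
  fd <- fd_error_gradients(st$sva_pred, obs$sv_fast, obs$sv_slow)
  st2 <- update_thresholds(st, obs)
  expect_equal(st2$t_fast - st$t_fast, -beta * fd[["de_dsv_fast"]],
               tolerance = 1e-8)
  expect_equal(st2$t_slow - st$t_slow, -beta * fd[["de_dsv_slow"]],
               tolerance = 1e-8)

  # clipping to the configured bounds
  sthi <- cerebellar_state(beta = 100, t_bounds = c(0.05, 1))
  st3 <- update_thresholds(sthi, obs)
  expect_gte(st3$t_fast, 0.05)
  expect_lte(st3$t_fast, 1)
  expect_gte(st3$t_slow, 0.05)
  expect_lte(st3$t_slow, 1)
})

test_that("heel-strike update uses the pre-update state and handles warm-up", {
  st <- cerebellar_state(alpha = 0.3, beta = 0.02)

  # warm-up: incomplete buffer is a flagged no-op
  res <- on_heel_strike(st, NULL)
  expect_true(res$diagnostics$warm_up)
  expect_equal(res$state$sva_pred, st$sva_pred)
  expect_equal(res$state$t_fast, st$t_fast)

  # zero-error fixed point: symmetric walking with matching prediction
  obs_sym <- step_observation(0.45, 0.45, 0.45, 0.45)
  res <- on_heel_strike(st, obs_sym)
  expect_false(res$diagnostics$warm_up)
  expect_equal(res$diagnostics$error, 0)
  expect_equal(res$state$sva_pred, st$sva_pred)
  expect_equal(res$state$t_fast, st$t_fast)
  expect_equal(res$state$t_slow, st$t_slow)

  # repeated identical observations: the second correction is strictly
  # smaller in magnitude (prediction has moved toward the observation)
  obs <- step_observation(0.285, 0.39, 0.45, 0.45)
  r1 <- on_heel_strike(st, obs)
  d1 <- abs(r1$state$sva_pred - st$sva_pred)
  r2 <- on_heel_strike(r1$state, obs)
  d2 <- abs(r2$state$sva_pred - r1$state$sva_pred)
  expect_lt(d2, d1)
  expect_lt(abs(r2$diagnostics$error), abs(r1$diagnostics$error))

  # threshold update is computed from the PRE-update prediction: manual
  # replay of the simultaneous update
  g <- error_gradients(st$sva_pred, obs$sv_fast, obs$sv_slow,
                       convention = st$convention)
  expect_equal(r1$state$t_fast,
               st$t_fast - st$beta * st$sensitivity[["fast"]] * g[["de_dsv_fast"]])
  sva <- step_velocity_asymmetry(obs$sv_fast, obs$sv_slow)
  expect_equal(r1$state$sva_pred, st$sva_pred - st$alpha * (st$sva_pred - sva))
})
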