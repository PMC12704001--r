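# Shared fixtures, built in code at test time.

# tied-belt baseline: equal belts, offsets, thresholds -> perfectly
# alternating symmetric gait
symmetric_fixture <- function(n_strides = 8L) {
  make_fixtures("symmetric_gait", list(n_strides = n_strides), seed = 42L)
}

# split-belt defaults, open loop (no adaptation)
splitbelt_fixture <- function(n_strides = 8L) {
  make_fixtures("splitbelt_gait", list(n_strides = n_strides), seed = 42L)
}

# central finite differences of the composed error
# e(p, f, s) = 0.5 * (p - (f - s)/(f + s))^2
fd_error_gradients <- function(p, f, s, h = 1e-6) {
  e <- function(p, f, s) prediction_error(p, step_velocity_asymmetry(f, s))
  c(de_dsv_slow = (e(p, f, s + h) - e(p, f, s - h)) / (2 * h),
    de_dsv_fast = (e(p, f + h, s) - e(p, f - h, s)) / (2 * h),
    de_dsva_pred = (e(p + h, f, s) - e(p - h, f, s)) / (2 * h))
}

# flat trajectory record walking in place for `tend` seconds
ideal_record <- function(tend = 10, tdes = tend, n = 201L, n_muscles = 14L) {
  tt <- seq(0, tend, length.out = n)
  trajectory_record(
    time = tt,
    com_height = rep(1, n),
    pelvis_x = rep(0, n),
    tilt_velocity = rep(0, n),
    activations = matrix(0, n, n_muscles),
    met_rate = 0,
    hs_times = list(slow = seq(0.5, tend, by = 0.9)),
    tend = tend, tdes = tdes)
}
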