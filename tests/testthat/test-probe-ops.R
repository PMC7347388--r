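make_band_frame <- function(center_col, ncol = 200, nrow = 60, sd = 3,
                            gain = 1, offset = 0) {
  img <- matrix(0, nrow, ncol)
  prof <- exp(-((seq_len(ncol)) - center_col)^2 / (2 * sd^2))
  for (r in seq_len(nrow)) img[r, ] <- prof
  img * gain + offset
}

test_that("probe tracking recovers a synthetic band to sub-pixel accuracy", {
  axis <- rbind(c(5, 30), c(195, 30))
  tp <- track_probe_position(make_band_frame(123.4), axis, pixel_size_um = 1)
  expect_true(tp$valid)
  expect_equal(tp$position_px + 5, 123.4, tolerance = 0.1)
})

test_that("probe tracking is translation-equivariant and scale-invariant", {
  axis <- rbind(c(5, 30), c(195, 30))
  p0 <- track_probe_position(make_band_frame(100), axis, pixel_size_um = 1.03)
  p1 <- track_probe_position(make_band_frame(110), axis, pixel_size_um = 1.03)
  expect_equal(p1$position_um - p0$position_um, 10 * 1.03, tolerance = 0.02)
  ps <- track_probe_position(make_band_frame(100, gain = 7.5, offset = 40),
                             axis, pixel_size_um = 1.03)
  expect_equal(ps$position_um, p0$position_um, tolerance = 1e-6)
})

test_that("a frame without an intensity peak is flagged, not an error", {
  axis <- rbind(c(5, 30), c(195, 30))
  tp <- track_probe_position(matrix(1, 60, 200), axis)
  expect_false(tp$valid)
  expect_true(is.na(tp$position_um))
})

test_that("spring-constant calibration is exact on noiseless data", {
  x <- seq(0, 400, length.out = 20)
  # summary.lm warns about the perfect fit; the slope is the point here
  cal <- suppressWarnings(calibrate_spring_constant(
    data.frame(position_um = x, force_uN = 0.2234 * x)))
  expect_equal(cal$k, 0.2234, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  zero <- suppressWarnings(calibrate_spring_constant(
    data.frame(position_um = x, force_uN = rep(0, 20))))
  expect_equal(zero$k, 0)
  expect_equal(zero$intercept, 0)
  expect_error(calibrate_spring_constant(
    data.frame(position_um = rep(1, 5), force_uN = 1:5)), "distinct")
})

test_that("calibration confidence intervals have near-nominal coverage", {
  x <- seq(0, 400, length.out = 50)
  covered <- vapply(1:500, function(s) {
    set.seed(s)
    f <- 0.2234 * x + rnorm(50, sd = 0.5)
    cal <- calibrate_spring_constant(data.frame(position_um = x, force_uN = f))
    ci <- cal$k + c(-1, 1) * qt(0.995, cal$n - 2) * cal$k_se
    ci[1] <= 0.2234 && 0.2234 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.97)
})

test_that("ring-down fit recovers the dynamical parameters", {
  pr <- probe_model()
  tt <- seq(0, 40, by = 1000 / 1200)
  x <- probe_step_oracle(tt, pr, 0, x0 = 100)
  ff <- fit_flick_dynamics(x, k = pr$k, fs = 1200)
  expect_false(ff$overdamped)
  expect_equal(ff$m, 0.1702, tolerance = 1e-4)
  expect_equal(ff$c, 0.1377, tolerance = 1e-4)
  expect_equal(ff$tau_ms, 2.47, tolerance = 0.01)
  expect_equal(ff$period_ms, 5.86, tolerance = 0.01)
  # fitted (m, c) reproduce the fitted (tau, omega_d) to machine precision
  expect_equal(2 * ff$m / ff$c, ff$tau_ms, tolerance = 1e-12)
  expect_equal(sqrt(pr$k / ff$m - (ff$c / (2 * ff$m))^2), ff$omega_d,
               tolerance = 1e-12)
})

test_that("ring-down fit tolerates measurement noise", {
  pr <- probe_model()
  tt <- seq(0, 40, by = 1000 / 1200)
  x0 <- probe_step_oracle(tt, pr, 0, x0 = 100)
  errs <- t(vapply(1:50, function(s) {
    set.seed(s)
    ff <- fit_flick_dynamics(x0 + rnorm(length(tt), sd = 1), k = pr$k, fs = 1200)
    c(abs(ff$m - pr$m) / pr$m, abs(ff$c - pr$c) / pr$c)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.05)
})

test_that("a non-oscillating release is flagged overdamped", {
  x <- 100 * exp(-(0:100) / 20)
  ff <- fit_flick_dynamics(x, k = 0.2, fs = 1200)
  expect_true(ff$overdamped)
})

test_that("quasistatic force is k times displacement", {
  pr <- probe_model()
  rec <- reconstruct_force(rep(50, 10), pr, fps = 170)
  expect_equal(rec$force_uN, rep(11.17, 10))
  zero <- reconstruct_force(rep(0, 10), pr, fps = 170)
  expect_true(all(zero$force_uN == 0))
})

test_that("drag and inertia are negligible at behavioral bandwidth", {
  pr <- probe_model()
  tt <- seq(0, 2, by = 1 / 170)
  x <- 100 * sin(2 * pi * 5 * tt)
  dyn <- reconstruct_force(x, pr, fps = 170, mode = "dynamic")$force_uN
  qs <- reconstruct_force(x, pr, fps = 170, mode = "quasistatic")$force_uN
  expect_lt(sqrt(mean((dyn - qs)^2)) / sqrt(mean(qs^2)), 0.02)
})

test_that("dynamic reconstruction inverts the probe model for slow forces", {
  pr <- probe_model()
  dt <- 2e-4
  tt <- seq(0, 5, by = dt)
  f <- 20 + 10 * sin(2 * pi * 3 * tt) + 5 * sin(2 * pi * 11 * tt + 1) +
    3 * sin(2 * pi * 27 * tt + 2) + 2 * sin(2 * pi * 45 * tt)
  resp <- simulate_probe_response(f, dt * 1000, pr)
  vid_t <- seq(0.2, 4.8, by = 1 / 170)   # skip the start-up transient
  x <- approx(tt, resp$displacement_um, xout = vid_t)$y
  f_vid <- approx(tt, f, xout = vid_t)$y
  rec <- reconstruct_force(x, pr, fps = 170, mode = "dynamic")$force_uN
  i <- 5:(length(rec) - 4)
  expect_lt(sqrt(mean((rec[i] - f_vid[i])^2)) / sqrt(mean(f_vid[i]^2)), 0.02)
})

test_that("dynamic mode rejects jittery frame times", {
  pr <- probe_model()
  set.seed(1)
  t_bad <- cumsum(runif(50, 1 / 200, 1 / 100))
  expect_error(
    reconstruct_force(rnorm(50), pr, frame_times_s = t_bad, mode = "dynamic"),
    "jitter"
  )
})
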