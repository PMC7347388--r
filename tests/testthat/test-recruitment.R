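flat_probe <- function(n = 1000, force = 5, fps = 170) {
  tibble::tibble(
    time_s = (seq_len(n) - 1) / fps,
    force_uN = rep(force, n),
    velocity_um_s = rep(0, n)
  )
}

test_that("a single spike over constant force centres on (F, 0)", {
  pb <- flat_probe()
  h <- spike_triggered_hist(1.0, pb, force_breaks = 5, velocity_breaks = 5)
  expect_equal(unname(h$centroid["force"]), 5)
  expect_equal(unname(h$centroid["velocity"]), 0)
  expect_error(spike_triggered_hist(numeric(), pb), "no spikes")
})

test_that("histogram counts are conserved and the centroid lies in the hull", {
  s <- simulate_session(sim_config(seed = 4, duration_s = 20),
                        include_traces = FALSE)
  for (ty in names(s$truth$spikes)) {
    h <- spike_triggered_hist(s$truth$spikes[[ty]], s$probe)
    expect_equal(sum(h$counts), h$n_frames)
    expect_gte(h$centroid["force"], min(h$force_edges))
    expect_lte(h$centroid["force"], max(h$force_edges))
    expect_gte(h$centroid["velocity"], min(h$velocity_edges))
    expect_lte(h$centroid["velocity"], max(h$velocity_edges))
  }
})

test_that("spikes planted at high velocity shift the triggered centroid", {
  s <- simulate_session(sim_config(seed = 9, duration_s = 20),
                        include_traces = FALSE)
  pb <- s$probe
  v0 <- quantile(pb$velocity_um_s, 0.9, na.rm = TRUE)
  fast_frames <- pb$time_s[which(pb$velocity_um_s > v0)]
  h <- spike_triggered_hist(fast_frames - 0.001, pb)
  expect_gt(h$centroid["velocity"], v0 * 0.5)
  # uniform spikes reproduce the whole-session centroid
  unif <- seq(0.5, 19.5, by = 0.05)
  hu <- spike_triggered_hist(unif, pb)
  expect_equal(unname(hu$centroid["force"]),
               mean(pb$force_uN, na.rm = TRUE),
               tolerance = 2 * sd(pb$force_uN, na.rm = TRUE) /
                 sqrt(length(unif)) * 5 + 0.05 * mean(pb$force_uN))
})

test_that("triggered centroid force is ordered fast > intermediate > slow", {
  s <- simulate_session(sim_config(seed = 21, duration_s = 30),
                        include_traces = FALSE)
  cf <- vapply(c("fast", "intermediate", "slow"), function(ty) {
    unname(spike_triggered_hist(s$truth$spikes[[ty]], s$probe)$centroid["force"])
  }, numeric(1))
  expect_gt(cf["fast"], cf["intermediate"])
  expect_gt(cf["intermediate"], cf["slow"])
})

test_that("preceding firing rate matches Poisson and regular-train oracles", {
  set.seed(5)
  a <- cumsum(rexp(3000, 30))          # ~30 Hz Poisson
  b <- runif(400, 1, max(a) - 1)
  est <- preceding_firing_rate(a, b, window_ms = 30)
  se <- sqrt(30 * 0.03) / 0.03 / sqrt(400)
  expect_lt(abs(est - 30), 2 * se)
  expect_equal(preceding_firing_rate(numeric(), b), 0)
  expect_error(preceding_firing_rate(a, numeric()), "no events")
  reg <- seq(0.01, 10, by = 0.01)      # exact 100 Hz
  b2 <- runif(100, 1, 9)
  est2 <- preceding_firing_rate(reg, b2, window_ms = 30)
  expect_lt(abs(est2 - 100), 1 / 0.03) # one-count quantisation
})

test_that("slow activity precedes fast recruitment above its session mean", {
  s <- simulate_session(sim_config(seed = 31, duration_s = 30),
                        include_traces = FALSE)
  slow <- s$truth$spikes$slow
  fast <- s$truth$spikes$fast
  pre <- preceding_firing_rate(slow, fast, window_ms = 30)
  expect_gt(pre, length(slow) / 30)
})

test_that("the force curve recovers gain, linearity and facilitation", {
  lin <- simulate_twitch_trials(rep(1:5, each = 3), force_per_spike_uN = 10,
                                facilitation = 1, seed = 2)
  fc <- force_per_spike_curve(lin)
  expect_equal(fc$slope_uN_per_spike, 10, tolerance = 0.02 * 10)
  expect_equal(fc$ratio_2_to_1, 2.0, tolerance = 0.02)
  fac <- simulate_twitch_trials(rep(1:5, each = 3), force_per_spike_uN = 10,
                                facilitation = 0.6, seed = 2)
  fcf <- force_per_spike_curve(fac)
  expect_equal(fcf$ratio_2_to_1, 1.6, tolerance = 0.05)
  zero <- simulate_twitch_trials(rep(1:3, each = 2), force_per_spike_uN = 0,
                                 seed = 3)
  expect_equal(force_per_spike_curve(zero)$slope_uN_per_spike, 0,
               tolerance = 1e-9)
  one_n <- simulate_twitch_trials(rep(2, 4), seed = 4)
  fc1 <- force_per_spike_curve(one_n)
  expect_true(is.na(fc1$slope_uN_per_spike))
  expect_equal(nrow(fc1$curve), 1)
})

test_that("gain recovery is stable across seeds at realistic noise", {
  slopes <- vapply(1:30, function(s) {
    tr <- simulate_twitch_trials(rep(1:4, each = 3), force_per_spike_uN = 10,
                                 facilitation = 1, noise_uN = 0.3, seed = s)
    force_per_spike_curve(tr)$slope_uN_per_spike
  }, numeric(1))
  expect_lt(abs(median(slopes) - 10) / 10, 0.05)
})

test_that("rise metrics match closed forms", {
  tt <- seq(0, 0.3, by = 1 / 1000)
  tau <- 0.02
  rm1 <- rise_metrics(1 - exp(-tt / tau), tt)
  expect_equal(rm1$t_half_ms, tau * log(2) * 1000, tolerance = 0.5)
  ramp <- c(seq(0, 1, length.out = 101), rep(1, 50))
  t2 <- seq_along(ramp) / 170
  rm2 <- rise_metrics(ramp, t2)
  expect_equal(rm2$max_velocity_per_s, 1 / (100 / 170), tolerance = 1e-6)
  step <- c(0, rep(1, 10))          # rise between the first two frames
  t3 <- (seq_along(step) - 1) / 170
  rm3 <- rise_metrics(step, t3)
  expect_lte(rm3$t_half_ms, 1000 / 170)
  expect_error(rise_metrics(rep(-1, 10), 1:10), "positive peak")
})
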