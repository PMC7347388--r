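test_that("preprocessing is band-pass on the derivative", {
  p <- spike_params()
  expect_true(all(abs(preprocess_trace(rep(3, 50000), p)) < 1e-8))
  # linear ramp: constant derivative, removed by the high-pass
  ramp <- seq(0, 1, length.out = 100000)
  out <- preprocess_trace(ramp, p)
  expect_lt(max(abs(tail(out, 50000))), 1e-6)
  amp_at <- function(freq) {
    tt <- seq(0, 0.5, by = 1 / 50000)
    max(abs(preprocess_trace(sin(2 * pi * freq * tt), p)[10000:20000]))
  }
  a20 <- amp_at(20); a500 <- amp_at(500); a5k <- amp_at(5000)
  expect_gt(a500, a20)
  expect_gt(a500, a5k)
})

test_that("cutoffs at or above Nyquist are rejected", {
  expect_error(spike_params(fs = 1000, hp_cutoff = 209, lp_cutoff = 898),
               "Nyquist")
  expect_error(spike_params(hp_cutoff = 1000, lp_cutoff = 898), "below")
})

test_that("DTW distance satisfies the metric-like axioms", {
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(40); b <- rnorm(40)
    d_ab <- dtw_distance(a, b)
    expect_gte(d_ab, 0)
    expect_equal(d_ab, dtw_distance(b, a), tolerance = 1e-12)
  }
  a <- rnorm(64)
  expect_identical(dtw_distance(a, a), 0)
  expect_error(dtw_distance(1:5, 1:6), "equal length")
})

test_that("DTW equals the brute-force dynamic-programming oracle exactly", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:64, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_identical(dtw_distance(a, b), dtw_oracle(a, b))
  }
})

test_that("warping absorbs small time shifts that Euclid cannot", {
  tt <- 1:100
  a <- exp(-((tt - 50)^2) / 30)
  b <- exp(-((tt - 55)^2) / 30)
  expect_lt(dtw_distance(a, b), 0.05 * sum((a - b)^2))
})

## a window-length event whose peak sits exactly at the window centre
centered_event <- function() {
  wf <- flymotor:::spike_waveform(50000)
  ev <- c(rep(0, 126 - which.max(wf)), wf, rep(0, 251))[1:251]
  stopifnot(which.max(ev) == 126)
  ev
}

test_that("template estimation averages and rejects gross outliers", {
  ev <- centered_event()
  filt <- rep(0, 60000)
  starts <- (0:9) * 5000 + 1000
  for (s in starts) filt[s:(s + 250)] <- ev
  junk <- sin(1:251 / 3) * 5
  filt[starts[4]:(starts[4] + 250)] <- junk
  peaks <- starts + 125L
  peaks[4] <- starts[4] + which.max(junk) - 1L
  tpl <- estimate_template(filt, peaks, window = 251)
  expect_true(peaks[4] %in% tpl$dropped)
  expect_equal(tpl$n_used, 9)
  # with identical seed events the template equals each event
  clean <- estimate_template(filt, peaks[-4], window = 251)
  expect_equal(clean$template, ev, tolerance = 1e-12)
  expect_error(estimate_template(filt, peaks[1:2], 251), "3 seed")
})

test_that("template averaging suppresses noise as 1/sqrt(n)", {
  set.seed(4)
  ev <- centered_event()
  filt <- rep(0, 100 * 500)
  peaks <- integer(100)
  for (i in 1:100) {
    s <- (i - 1L) * 500L + 100L
    filt[s:(s + 250L)] <- ev + rnorm(251, sd = 0.2)
    peaks[i] <- s + 125L
  }
  tpl <- estimate_template(filt, peaks, window = 251)
  rmse <- sqrt(mean((tpl$template - ev)^2))
  expect_lt(rmse, 0.2 / 8)
})

test_that("the detector finds every inserted spike and nothing else", {
  st <- simulate_spike_trace(duration_s = 10, rate_hz = 2, snr = 10, seed = 4)
  sp <- detect_spikes(st$trace, params = spike_params())
  m <- match_times(sp$peak_s, st$spike_times_s, tol_s = 1e-3)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["precision"]), 1)
  expect_true(all(sp$onset_index <= sp$peak_index))
  expect_true(all(diff(sp$peak_index) > 0))
})

test_that("pure noise yields no accepted spikes at default cutoffs", {
  set.seed(9)
  noise <- rnorm(10 * 50000)
  sp <- detect_spikes(noise, params = spike_params())
  expect_equal(nrow(sp), 0)
})

test_that("detection is invariant to trace offset and equivariant to scale", {
  st <- simulate_spike_trace(duration_s = 5, rate_hz = 3, snr = 10, seed = 6)
  sp0 <- detect_spikes(st$trace, params = spike_params())
  sp_off <- detect_spikes(st$trace - 60, params = spike_params())
  expect_equal(sp_off$peak_index, sp0$peak_index)
  expect_equal(sp_off$amplitude, sp0$amplitude, tolerance = 1e-9)
  sp_scaled <- detect_spikes(st$trace * 3, params = spike_params())
  expect_equal(sp_scaled$peak_index, sp0$peak_index)
  expect_equal(sp_scaled$amplitude, 3 * sp0$amplitude, tolerance = 1e-9)
})

test_that("EMG polarity inversion recovers negative-going events", {
  st <- simulate_spike_trace(duration_s = 5, rate_hz = 3, snr = 10, seed = 8)
  sp <- detect_spikes(-st$trace,
                      params = spike_params(invert = TRUE))
  m <- match_times(sp$peak_s, st$spike_times_s, tol_s = 1e-3)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["precision"]), 1)
})

test_that("tightening the shape cutoff never increases acceptances", {
  st <- simulate_spike_trace(duration_s = 5, rate_hz = 4, snr = 6, seed = 10)
  sp_auto <- detect_spikes(st$trace, params = spike_params())
  cand <- attr(sp_auto, "candidates")
  cuts <- quantile(cand$shape_distance, c(0.9, 0.6, 0.3, 0.1))
  n_at <- vapply(cuts, function(cc) {
    nrow(detect_spikes(st$trace, template = attr(sp_auto, "template"),
                       params = spike_params(shape_cutoff = cc,
                                             amp_cutoff = -Inf)))
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("onset localisation lands at the point of maximal acceleration", {
  fs <- 50000
  tt <- seq(-0.01, 0.01, by = 1 / fs)
  s <- 0.0008
  sig <- 1 / (1 + exp(-tt / s))
  peak <- which.max(diff(sig)) + 1L  # top of the rise
  onset <- locate_onset(sig, which(tt >= 0.005)[1], onset_smooth = 5,
                        search = 400)
  # analytic max of the second derivative of a logistic at t = -1.317 s
  t_true <- -1.3170 * s
  expect_lt(abs(tt[onset] - t_true), 3 / fs)
  # triangle pulse: onset at the rising-edge kink
  tri <- c(rep(0, 200), seq(0, 1, length.out = 100),
           seq(1, 0, length.out = 100), rep(0, 100))
  on_tri <- locate_onset(tri, 300, onset_smooth = 3, search = 150)
  expect_lt(abs(on_tri - 200), 5)
  # bounded output on pure noise
  set.seed(2)
  nz <- rnorm(1000)
  on_nz <- locate_onset(nz, 600, search = 125)
  expect_true(on_nz <= 600 && on_nz >= 475)
  expect_error(locate_onset(nz, 2), "boundary")
})
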