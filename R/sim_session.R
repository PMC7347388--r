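#' Configuration for a synthetic recording session
#'
#' Bundles all parameters of the synthetic-session generator. Defaults are
#' the study conditions: three tibia flexor motor neuron types with resting
#' potentials -48/-60/-68 mV (slow/intermediate/fast), a tonic ~30 Hz
#' resting rate in the slow neuron only, per-spike forces spanning three
#' orders of magnitude (<0.1 uN for slow, ~1 uN intermediate, ~10 uN fast),
#' ephys digitised at 50 kHz, probe video at 170 Hz, calcium at 50 Hz, and
#' the calibrated probe model.
#'
#' The common drive is a smoothed random telegraph process on \[0, 1\];
#' intermediate and fast neurons only fire above their drive thresholds,
#' which builds the recruitment order (slow, then intermediate, then fast)
#' into the ground truth. The first three drive segments visit the low,
#' medium and high levels in random order so all three regimes occur even
#' in short sessions.
#'
#' @param seed Integer seed; fixes all randomness of the session.
#' @param duration_s Session duration in seconds.
#' @param fs_ephys,fps_video,fps_calcium Sampling rates (Hz); must satisfy
#'   `fps_calcium < fps_video < fs_ephys`.
#' @param probe A [probe_model()].
#' @param neurons Data frame of per-type parameters (see Details); defaults
#'   supplied by `default_neuron_params()`.
#' @param gcamp List with `rise_ms`, `decay_ms` of the calcium indicator
#'   kernel (difference of exponentials).
#' @param geometry List with `lever_arm_um`, `azimuth_deg`, `arc_radius_px`.
#' @param drive List with `levels` (telegraph levels), `dwell_s` (mean
#'   segment duration), `smooth_ms` (Gaussian smoothing s.d.).
#' @param facilitation Per-spike force increment ratio within a burst; the
#'   n-th spike of a burst contributes `facilitation^(n-1)` of the first
#'   spike's force, so two near-coincident spikes peak at ~1.6x one spike
#'   at the default 0.6. Set to 1 for linear summation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 60,
                       fs_ephys = 50000,
                       fps_video = 170,
                       fps_calcium = 50,
                       probe = probe_model(),
                       neurons = default_neuron_params(),
                       gcamp = list(rise_ms = 50, decay_ms = 300),
                       geometry = list(lever_arm_um = 417, azimuth_deg = 60,
                                       arc_radius_px = 100),
                       drive = list(levels = c(0, 0.55, 0.95), dwell_s = 2,
                                    smooth_ms = 100),
                       facilitation = 0.6) {
  check_number(duration_s, "duration_s", positive = TRUE)
  check_number(fs_ephys, "fs_ephys", positive = TRUE)
  check_number(fps_video, "fps_video", positive = TRUE)
  check_number(fps_calcium, "fps_calcium", positive = TRUE)
  if (!(fps_calcium < fps_video && fps_video < fs_ephys)) {
    abort("rates must satisfy fps_calcium < fps_video < fs_ephys.")
  }
  if (!inherits(probe, "probe_model")) abort("`probe` must be a probe_model.")
  needed <- c("type", "rest_mv", "rate_hz", "drive_gain_hz", "threshold",
              "force_per_spike_uN", "spike_amp_mv", "noise_sd_mv",
              "twitch_rise_ms", "twitch_decay_ms")
  if (!all(needed %in% names(neurons))) {
    abort(paste("`neurons` must have columns:", paste(needed, collapse = ", ")))
  }
  structure(
    list(seed = as.integer(seed), duration_s = duration_s,
         fs_ephys = fs_ephys, fps_video = fps_video,
         fps_calcium = fps_calcium, probe = probe,
         neurons = tibble::as_tibble(neurons), gcamp = gcamp,
         geometry = geometry, drive = drive, facilitation = facilitation),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_neuron_params <- function() {
  tibble::tibble(
    type = c("slow", "intermediate", "fast"),
    rest_mv = c(-48, -60, -68),
    rate_hz = c(30, 0, 0),          # tonic rate at zero drive
    drive_gain_hz = c(60, 120, 80), # extra rate per unit supra-threshold drive
    threshold = c(0, 0.45, 0.75),   # drive level where the unit recruits
    force_per_spike_uN = c(0.08, 1, 10),
    spike_amp_mv = c(4, 8, 12),
    noise_sd_mv = c(0.4, 0.4, 0.4),
    twitch_rise_ms = c(20, 3, 3),
    twitch_decay_ms = c(200, 40, 40)
  )
}

# biexponential spike waveform (~2 ms wide), unit peak, sampled at fs
spike_waveform <- function(fs, rise_ms = 0.2, decay_ms = 0.6, span_ms = 5) {
  tt <- seq(0, span_ms, by = 1000 / fs)
  w <- exp(-tt / decay_ms) - exp(-tt / rise_ms)
  w / max(w)
}

# homogeneous/inhomogeneous Poisson spikes by per-bin thinning on grid `dt_s`,
# with an absolute refractory period
poisson_spikes <- function(rate_hz, dt_s, refractory_ms = 2) {
  p <- pmin(rate_hz * dt_s, 1)
  hit <- which(runif(length(p)) < p)
  if (length(hit) <= 1L) return(hit)
  t_ms <- hit * dt_s * 1000
  keep <- rep(TRUE, length(hit))
  last <- t_ms[1L]
  for (i in seq_along(hit)[-1L]) {
    if (t_ms[i] - last < refractory_ms) keep[i] <- FALSE else last <- t_ms[i]
  }
  hit[keep]
}

# facilitation weights: spike n of a burst (ISIs < reset_ms) carries
# fac^(n-1); force summation is then linear in these weighted impulses
facilitation_weights <- function(times_s, fac, reset_ms = 100) {
  if (length(times_s) == 0L) return(numeric())
  w <- numeric(length(times_s))
  pos <- 0L
  for (i in seq_along(times_s)) {
    pos <- if (i == 1L || (times_s[i] - times_s[i - 1L]) * 1000 > reset_ms) {
      1L
    } else {
      pos + 1L
    }
    w[i] <- fac^(pos - 1L)
  }
  w
}

#' Simulate a full recording session with ground truth
#'
#' Generates a seeded synthetic session emulating the study's simultaneous
#' recordings: spike trains for the slow, intermediate and fast motor
#' neurons driven by a common smoothed-telegraph drive signal (the slow
#' neuron fires tonically and modulates with drive; the others recruit
#' above increasing drive thresholds); per-spike muscle twitches with
#' facilitation summed into a force input; probe displacement obtained by
#' integrating the second-order probe model; and optionally 50 kHz
#' whole-cell voltage and EMG traces with one spike waveform inserted per
#' ground-truth spike.
#'
#' Within every high-drive epoch the generator enforces recruitment order
#' on the ground truth: no intermediate spike before the first slow spike
#' of the epoch and no fast spike before the first intermediate spike.
#'
#' @param config A [sim_config()].
#' @param include_traces If `FALSE`, skip synthesis of the 50 kHz traces
#'   (cheaper when only spike times and probe dynamics are needed).
#' @return A list of class `fm_session` with elements `probe` (tibble at
#'   video rate: `time_s`, `displacement_um`, `force_uN`, `velocity_um_s`),
#'   `voltage` (tibble at 50 kHz, one column per neuron type, if requested),
#'   `emg` (tibble, if requested), `truth` (list: `spikes` named list of
#'   spike times in s, `epochs` tibble of high-drive epochs, `drive` tibble,
#'   `force_input` tibble, `waveforms_inserted` named counts) and `config`.
#' @examples
#' s <- simulate_session(sim_config(seed = 2, duration_s = 5), include_traces = FALSE)
#' lengths(s$truth$spikes)
#' @export
simulate_session <- function(config = sim_config(), include_traces = TRUE) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  with_seed(config$seed, {
    dur <- config$duration_s
    dt_f <- 2e-4                                  # force/drive grid (s)
    tt <- seq(0, dur, by = dt_f)
    nt <- length(tt)

    ## ---- common drive: smoothed random telegraph --------------------
    levels <- config$drive$levels
    n_seg <- max(8L, ceiling(dur / config$drive$dwell_s * 3))
    seg_len <- rexp(n_seg, rate = 1 / config$drive$dwell_s)
    seg_lvl <- if (length(levels) == 1L) {
      rep(levels, n_seg)
    } else {
      c(sample(levels), sample(levels, n_seg - length(levels), replace = TRUE))
    }
    seg_end <- cumsum(seg_len)
    seg_idx <- findInterval(tt, c(0, seg_end), left.open = TRUE)
    drive_raw <- seg_lvl[pmin(pmax(seg_idx, 1L), n_seg)]
    sm_sd <- config$drive$smooth_ms / 1000 / dt_f  # in samples
    if (sm_sd > 0) {
      r <- ceiling(3 * sm_sd)
      kk <- exp(-((-r:r)^2) / (2 * sm_sd^2)); kk <- kk / sum(kk)
      pad <- c(rep(drive_raw[1L], r), drive_raw, rep(drive_raw[nt], r))
      drive <- as.numeric(stats::filter(pad, kk, sides = 2L))[(r + 1L):(r + nt)]
    } else {
      drive <- drive_raw
    }

    ## ---- spike trains with recruitment structure --------------------
    nrn <- config$neurons
    refr_ms <- 2
    spikes <- lapply(seq_len(nrow(nrn)), function(i) {
      rate <- nrn$rate_hz[i] + nrn$drive_gain_hz[i] * pmax(0, drive - nrn$threshold[i])
      rate[drive < nrn$threshold[i] & nrn$rate_hz[i] == 0] <- 0
      # compensate the Poisson intensity for refractory deletions so the
      # realised rate matches the nominal one
      rate <- rate / pmax(1e-6, 1 - rate * refr_ms / 1000)
      idx <- poisson_spikes(rate, dt_f, refractory_ms = refr_ms)
      tt[idx]
    })
    names(spikes) <- nrn$type

    thr_int <- nrn$threshold[nrn$type == "intermediate"]
    thr_fast <- nrn$threshold[nrn$type == "fast"]
    # enforce first-slow <= first-intermediate within supra-intermediate runs
    runs_int <- true_runs(drive > thr_int)
    if (nrow(runs_int) > 0 && length(spikes$intermediate) > 0) {
      keep <- rep(TRUE, length(spikes$intermediate))
      for (r in seq_len(nrow(runs_int))) {
        t0 <- tt[runs_int[r, 1L]]; t1 <- tt[runs_int[r, 2L]]
        in_run <- spikes$intermediate >= t0 & spikes$intermediate <= t1
        sl <- spikes$slow[spikes$slow >= t0 & spikes$slow <= t1]
        first_sl <- if (length(sl)) min(sl) else Inf
        keep[in_run & spikes$intermediate < first_sl] <- FALSE
      }
      spikes$intermediate <- spikes$intermediate[keep]
    }
    # within each high-drive epoch: no intermediate spike before the first
    # slow spike of the epoch, then no fast spike before the first
    # intermediate spike of the epoch
    runs_fast <- true_runs(drive > thr_fast)
    if (nrow(runs_fast) > 0) {
      for (r in seq_len(nrow(runs_fast))) {
        t0 <- tt[runs_fast[r, 1L]]; t1 <- tt[runs_fast[r, 2L]]
        sl <- spikes$slow[spikes$slow >= t0 & spikes$slow <= t1]
        first_sl <- if (length(sl)) min(sl) else Inf
        drop_im <- spikes$intermediate >= t0 & spikes$intermediate <= t1 &
          spikes$intermediate < first_sl
        spikes$intermediate <- spikes$intermediate[!drop_im]
        im <- spikes$intermediate[spikes$intermediate >= t0 &
                                    spikes$intermediate <= t1]
        first_im <- if (length(im)) min(im) else Inf
        drop_f <- spikes$fast >= t0 & spikes$fast <= t1 & spikes$fast < first_im
        spikes$fast <- spikes$fast[!drop_f]
      }
    }
    epochs <- tibble::tibble(
      start_s = tt[runs_fast[, 1L]],
      end_s = tt[runs_fast[, 2L]]
    )

    ## ---- muscle force input and probe response ----------------------
    force <- numeric(nt)
    for (i in seq_len(nrow(nrn))) {
      st <- spikes[[nrn$type[i]]]
      if (length(st) == 0L) next
      w <- facilitation_weights(st, config$facilitation)
      train <- numeric(nt)
      bins <- pmin(nt, floor(st / dt_f) + 1L)
      for (j in seq_along(bins)) train[bins[j]] <- train[bins[j]] + w[j]
      kern <- doe_kernel(nrn$twitch_rise_ms[i], nrn$twitch_decay_ms[i],
                         dt_f * 1000)
      force <- force + nrn$force_per_spike_uN[i] * causal_conv(train, kern)
    }
    disp <- .probe_rk4(force, dt_f * 1000, config$probe$k, config$probe$m,
                       config$probe$c, 0, 0, 0.05)

    video_times <- seq(0, dur, by = 1 / config$fps_video)
    x_vid <- approx(tt, disp, xout = video_times, rule = 2)$y
    probe_tbl <- tibble::tibble(
      time_s = video_times,
      displacement_um = x_vid,
      force_uN = config$probe$k * x_vid,
      velocity_um_s = probe_velocity(x_vid, config$fps_video)
    )

    ## ---- electrophysiology traces ------------------------------------
    voltage <- NULL
    emg <- NULL
    inserted <- setNames(integer(nrow(nrn)), nrn$type)
    if (include_traces) {
      ne <- floor(dur * config$fs_ephys) + 1L
      te <- (seq_len(ne) - 1) / config$fs_ephys
      wf <- spike_waveform(config$fs_ephys)
      drive_e <- approx(tt, drive, xout = te, rule = 2)$y
      vcols <- list()
      for (i in seq_len(nrow(nrn))) {
        v <- nrn$rest_mv[i] + 8 * drive_e +
          rnorm(ne, sd = nrn$noise_sd_mv[i])
        idx <- floor(spikes[[nrn$type[i]]] * config$fs_ephys) + 1L
        idx <- idx[idx + length(wf) - 1L <= ne]
        for (s0 in idx) {
          rng <- s0:(s0 + length(wf) - 1L)
          v[rng] <- v[rng] + nrn$spike_amp_mv[i] * wf
        }
        inserted[nrn$type[i]] <- length(idx)
        vcols[[nrn$type[i]]] <- v
      }
      voltage <- tibble::as_tibble(c(list(time_s = te), vcols))
      e <- rnorm(ne, sd = 1)
      for (ty in c("intermediate", "fast")) {
        amp <- if (ty == "fast") 100 else 20
        idx <- floor(spikes[[ty]] * config$fs_ephys) + 1L
        idx <- idx[idx + length(wf) - 1L <= ne]
        for (s0 in idx) {
          rng <- s0:(s0 + length(wf) - 1L)
          e[rng] <- e[rng] + amp * wf
        }
      }
      emg <- tibble::tibble(time_s = te, emg = e)
    }

    structure(
      list(
        probe = probe_tbl,
        voltage = voltage,
        emg = emg,
        truth = list(
          spikes = spikes,
          epochs = epochs,
          drive = tibble::tibble(time_s = tt, drive = drive),
          force_input = tibble::tibble(time_s = tt, force_uN = force),
          waveforms_inserted = inserted
        ),
        config = config
      ),
      class = "fm_session"
    )
  })
}

#' @export
print.fm_session <- function(x, ...) {
  cat(sprintf("<fm_session> %.1f s, seed %d\n", x$config$duration_s,
              x$config$seed))
  cat("  spikes:", paste(sprintf("%s = %d", names(x$truth$spikes),
                                 lengths(x$truth$spikes)), collapse = ", "), "\n")
  invisible(x)
}

#' Probe velocity from tracked positions
#'
#' Central-difference velocity of a displacement trace at the video rate,
#' after Savitzky-Golay smoothing (window 5, order 2) to suppress tracking
#' jitter.
#'
#' @param positions_um Displacement trace (um).
#' @param fps Frame rate (Hz).
#' @return Velocity in um/s, same length as the input.
#' @export
probe_velocity <- function(positions_um, fps) {
  x <- as.numeric(positions_um)
  n <- length(x)
  if (n < 5L) return(rep(NA_real_, n))
  xs <- signal::sgolayfilt(x, p = 2, n = 5)
  v <- c(xs[2L] - xs[1L], (xs[3:n] - xs[1:(n - 2L)]) / 2, xs[n] - xs[n - 1L])
  v * fps
}

#' Simulate a single-unit 50 kHz trace with inserted spikes
#'
#' A light-weight generator for benchmarking the spike detector: a
#' Gaussian-noise baseline with biexponential spike waveforms inserted at
#' Poisson times (with refractory period), at a chosen signal-to-noise
#' ratio. Ground-truth spike times are returned.
#'
#' @param duration_s,fs Trace duration (s) and sampling rate (Hz).
#' @param rate_hz Mean spike rate.
#' @param snr Spike amplitude divided by noise s.d.
#' @param noise_sd Noise standard deviation (trace units).
#' @param refractory_ms Minimum spacing between ground-truth spikes.
#' @param seed Integer seed.
#' @return List with `trace`, `fs`, `spike_times_s`, `spike_peak_idx`
#'   (index of each inserted waveform's peak) and `waveform`.
#' @export
simulate_spike_trace <- function(duration_s = 60, fs = 50000, rate_hz = 2,
                                 snr = 10, noise_sd = 1, refractory_ms = 3,
                                 seed = 1L) {
  with_seed(seed, {
    n <- floor(duration_s * fs)
    wf <- spike_waveform(fs)
    peak_off <- which.max(wf) - 1L
    margin_s <- (length(wf) + 1) / fs
    idx <- poisson_spikes(rep(rate_hz, n), 1 / fs, refractory_ms = refractory_ms)
    st <- idx / fs
    st <- st[st > margin_s & st < duration_s - margin_s]
    trace <- rnorm(n, sd = noise_sd)
    start <- floor(st * fs) + 1L
    for (s0 in start) {
      rng <- s0:(s0 + length(wf) - 1L)
      trace[rng] <- trace[rng] + snr * noise_sd * wf
    }
    list(trace = trace, fs = fs, spike_times_s = (start - 1L + peak_off) / fs,
         spike_peak_idx = start + peak_off, waveform = wf)
  })
}

#' Simulate spike-count trials of probe force responses
#'
#' Emulates the optogenetic force-per-spike experiments: each trial drives
#' `n` spikes at short intra-burst intervals (default 1 ms, short relative
#' to the ~8 ms twitch rise so that peak forces superpose), converts the
#' summed twitches to probe displacement through the probe model, and
#' returns the baseline-subtracted force trace sampled at `fs_out`.
#'
#' @param n_spikes Integer vector: number of spikes per trial (one trial
#'   per element; repeat values for replicate trials).
#' @param force_per_spike_uN Force increment of the first spike (uN).
#' @param facilitation Burst increment ratio (1 = linear summation;
#'   0.6 gives a two-spike/one-spike peak ratio of ~1.6).
#' @param isi_ms Intra-burst inter-spike interval (ms).
#' @param twitch_rise_ms,twitch_decay_ms Twitch kernel time constants.
#' @param probe A [probe_model()].
#' @param fs_out Output sampling rate (Hz).
#' @param trial_dur_s Trial duration (s); spikes start at 50 ms.
#' @param noise_uN Gaussian noise s.d. added to the force trace.
#' @param seed Integer seed.
#' @return A tibble with one row per trial: `trial`, `n_spikes`, and
#'   list-columns `time_s` and `force` (baseline-subtracted force, uN),
#'   ready for [force_per_spike_curve()].
#' @export
simulate_twitch_trials <- function(n_spikes, force_per_spike_uN = 10,
                                   facilitation = 0.6, isi_ms = 1,
                                   twitch_rise_ms = 3, twitch_decay_ms = 40,
                                   probe = probe_model(), fs_out = 1000,
                                   trial_dur_s = 0.5, noise_uN = 0,
                                   seed = 1L) {
  with_seed(seed, {
    dt_f <- 2e-4
    tt <- seq(0, trial_dur_s, by = dt_f)
    kern <- doe_kernel(twitch_rise_ms, twitch_decay_ms, dt_f * 1000)
    out_t <- seq(0, trial_dur_s, by = 1 / fs_out)
    rows <- purrr::map(seq_along(n_spikes), function(i) {
      n <- n_spikes[i]
      train <- numeric(length(tt))
      if (n > 0) {
        st <- 0.05 + (seq_len(n) - 1) * isi_ms / 1000
        w <- facilitation^(seq_len(n) - 1)
        bins <- floor(st / dt_f) + 1L
        for (j in seq_len(n)) train[bins[j]] <- train[bins[j]] + w[j]
      }
      force_in <- force_per_spike_uN * causal_conv(train, kern)
      x <- .probe_rk4(force_in, dt_f * 1000, probe$k, probe$m, probe$c,
                      0, 0, 0.05)
      f_probe <- probe$k * approx(tt, x, xout = out_t, rule = 2)$y
      if (noise_uN > 0) f_probe <- f_probe + rnorm(length(f_probe), sd = noise_uN)
      tibble::tibble(trial = i, n_spikes = n,
                     time_s = list(out_t), force = list(f_probe))
    })
    dplyr::bind_rows(rows)
  })
}
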