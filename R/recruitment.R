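#' Spike-triggered 2-D histogram of probe force and velocity
#'
#' Collects every video frame falling in the window (default 25 ms)
#' following each spike and bins the probe force and velocity of those
#' frames into a 2-D histogram, the signature analysis of recruitment
#' regimes: each motor neuron type tends to spike in a distinct region of
#' force-velocity space. The mass-weighted centroid is computed from the
#' raw contributing frame values (before any log display scaling). Frames
#' shared by overlapping spike windows are counted once per contributing
#' window by default (`dedupe = TRUE` counts them once overall).
#'
#' @param spike_times_s Spike times (s).
#' @param probe Data frame with columns `time_s`, `force_uN` and
#'   `velocity_um_s` (e.g. the `probe` element of an `fm_session`).
#' @param window_ms Post-spike window length.
#' @param force_breaks,velocity_breaks Bin edges, or a single bin count.
#' @param dedupe Count frames once even when windows overlap.
#' @param exclude_bins Optional data frame of `force_bin`, `velocity_bin`
#'   indices to mask (stationary hotspots); masked bins are zeroed in the
#'   counts and excluded from the centroid.
#' @return An object of class `fm_hist2d`: `counts` matrix (force bins x
#'   velocity bins), `force_edges`, `velocity_edges`, `centroid` (named
#'   vector: force, velocity), `n_frames`, `log_density`.
#' @export
spike_triggered_hist <- function(spike_times_s, probe, window_ms = 25,
                                 force_breaks = 20, velocity_breaks = 20,
                                 dedupe = FALSE, exclude_bins = NULL) {
  if (length(spike_times_s) == 0L) abort("no spikes: cannot build a histogram.")
  if (!all(c("time_s", "force_uN", "velocity_um_s") %in% names(probe))) {
    abort("`probe` needs columns time_s, force_uN, velocity_um_s.")
  }
  w <- window_ms / 1000
  idx <- lapply(spike_times_s, function(s) {
    which(probe$time_s > s & probe$time_s <= s + w)
  })
  idx <- unlist(idx)
  if (dedupe) idx <- unique(idx)
  if (length(idx) == 0L) abort("no video frames fall in any spike window.")
  f <- probe$force_uN[idx]
  v <- probe$velocity_um_s[idx]
  ok <- is.finite(f) & is.finite(v)
  f <- f[ok]; v <- v[ok]
  edges <- function(vals, br) {
    if (length(br) == 1L) seq(min(vals), max(vals), length.out = br + 1L) else br
  }
  fe <- edges(f, force_breaks)
  ve <- edges(v, velocity_breaks)
  fb <- pmin(pmax(findInterval(f, fe, all.inside = TRUE), 1L), length(fe) - 1L)
  vb <- pmin(pmax(findInterval(v, ve, all.inside = TRUE), 1L), length(ve) - 1L)
  counts <- matrix(0, length(fe) - 1L, length(ve) - 1L)
  for (i in seq_along(fb)) counts[fb[i], vb[i]] <- counts[fb[i], vb[i]] + 1
  mask_keep <- rep(TRUE, length(f))
  if (!is.null(exclude_bins)) {
    for (r in seq_len(nrow(exclude_bins))) {
      hit <- fb == exclude_bins$force_bin[r] & vb == exclude_bins$velocity_bin[r]
      mask_keep[hit] <- FALSE
      counts[exclude_bins$force_bin[r], exclude_bins$velocity_bin[r]] <- 0
    }
  }
  centroid <- c(force = mean(f[mask_keep]), velocity = mean(v[mask_keep]))
  structure(
    list(counts = counts, force_edges = fe, velocity_edges = ve,
         centroid = centroid, n_frames = sum(counts),
         log_density = log1p(counts) / max(log1p(counts))),
    class = "fm_hist2d"
  )
}

#' @export
print.fm_hist2d <- function(x, ...) {
  cat(sprintf("<fm_hist2d> %d frames; centroid force = %.3g uN, velocity = %.3g um/s\n",
              x$n_frames, x$centroid["force"], x$centroid["velocity"]))
  invisible(x)
}

#' Firing rate of one neuron preceding another neuron's spikes
#'
#' For each event in train B, counts the spikes of train A in the window
#' preceding it (default 30 ms) and returns the mean count divided by the
#' window — the recruitment-hierarchy diagnostic: units lower in the
#' hierarchy should already be firing when a stronger unit recruits.
#'
#' @param reference_times_s Spike times of the reference train A (s).
#' @param event_times_s Event times B (s).
#' @param window_ms Look-back window.
#' @return Mean preceding rate of A (Hz). 0 if A is empty; error if B is.
#' @export
preceding_firing_rate <- function(reference_times_s, event_times_s,
                                  window_ms = 30) {
  if (length(event_times_s) == 0L) abort("no events in train B.")
  if (length(reference_times_s) == 0L) return(0)
  w <- window_ms / 1000
  counts <- vapply(event_times_s, function(t0) {
    sum(reference_times_s >= t0 - w & reference_times_s < t0)
  }, numeric(1))
  mean(counts) / w
}

#' Peak force versus spike count
#'
#' Reproduces the force-per-spike analysis: trials are grouped by spike
#' count, aligned traces are averaged within each count, and the peak of
#' each average gives one point of the force curve. A free-intercept
#' linear fit of peak force against spike count gives the gain
#' (uN/spike); the two-spike to one-spike peak ratio quantifies
#' facilitation (~1.6 for fast and intermediate motor units).
#'
#' @param trials Data frame with columns `n_spikes` and list-column
#'   `force` (baseline-subtracted, time-aligned force traces of equal
#'   length), e.g. from [simulate_twitch_trials()].
#' @return An object of class `fm_force_curve`: `curve` tibble
#'   (`n_spikes`, `peak_force_uN`, `n_trials`), `slope_uN_per_spike`
#'   (`NA` when all trials share one count), `ratio_2_to_1`, `fit`.
#' @export
force_per_spike_curve <- function(trials) {
  if (!all(c("n_spikes", "force") %in% names(trials))) {
    abort("`trials` needs columns n_spikes and force (list of traces).")
  }
  curve <- trials |>
    dplyr::group_by(.data$n_spikes) |>
    dplyr::summarise(
      peak_force_uN = {
        m <- colMeans(do.call(rbind, .data$force))
        max(m)
      },
      n_trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$n_spikes)
  fit <- NULL
  slope <- NA_real_
  if (nrow(curve) >= 2L) {
    fit <- lm(peak_force_uN ~ n_spikes, data = curve)
    slope <- unname(coef(fit)[2L])
  }
  ratio <- if (all(c(1, 2) %in% curve$n_spikes)) {
    curve$peak_force_uN[curve$n_spikes == 2] /
      curve$peak_force_uN[curve$n_spikes == 1]
  } else NA_real_
  structure(
    list(curve = curve, slope_uN_per_spike = slope, ratio_2_to_1 = ratio,
         fit = fit),
    class = "fm_force_curve"
  )
}

#' @export
print.fm_force_curve <- function(x, ...) {
  cat(sprintf("<fm_force_curve> %d spike counts; slope = %.3g uN/spike, 2:1 ratio = %.3g\n",
              nrow(x$curve), x$slope_uN_per_spike, x$ratio_2_to_1))
  invisible(x)
}

#' Rise kinetics of an average force/displacement transient
#'
#' `t_half` is the first time the trace crosses half its peak (linear
#' interpolation between samples). `max_velocity` is the slope of a
#' least-squares line fitted to the rising-phase samples between 10% and
#' 90% of the peak — the analysis used to estimate maximum movement speed
#' per motor neuron type.
#'
#' @param trace Baseline-subtracted average trace (positive peak).
#' @param time_s Sample times (s).
#' @return A one-row tibble: `t_half_ms`, `max_velocity_per_s` (trace
#'   units per second).
#' @export
rise_metrics <- function(trace, time_s) {
  x <- as.numeric(trace)
  if (length(x) != length(time_s)) abort("`trace` and `time_s` lengths differ.")
  pk <- max(x)
  if (pk <= 0) abort("trace has no positive peak.")
  ip <- which.max(x)
  half <- pk / 2
  below <- which(x[seq_len(ip)] < half)
  t_half <- if (length(below) == 0L) {
    time_s[1L]
  } else {
    i0 <- max(below)
    # linear interpolation between the straddling samples
    time_s[i0] + (half - x[i0]) / (x[i0 + 1L] - x[i0]) *
      (time_s[i0 + 1L] - time_s[i0])
  }
  rise <- seq_len(ip)
  sel <- rise[x[rise] >= 0.1 * pk & x[rise] <= 0.9 * pk]
  vmax <- if (length(sel) >= 2L) {
    unname(coef(lm(x[sel] ~ time_s[sel]))[2L])
  } else {
    # step-like rise: slope across the straddling frame interval
    (x[ip] - x[max(1L, ip - 1L)]) /
      (time_s[ip] - time_s[max(1L, ip - 1L)])
  }
  tibble::tibble(t_half_ms = (t_half - time_s[1L]) * 1000,
                 max_velocity_per_s = vmax)
}
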