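#' Spike detection parameters
#'
#' Parameters for the four-step template spike detector used on 50 kHz
#' whole-cell and EMG traces: (1) band-pass filter the first derivative,
#' (2) find candidate peaks above a threshold, (3) score each candidate's
#' shape against a template by dynamic time warping, (4) accept candidates
#' that pass both the shape and the raw-amplitude cutoffs.
#'
#' @param fs Sampling rate (Hz).
#' @param hp_cutoff,lp_cutoff High-/low-pass corner frequencies (Hz) of the
#'   cascaded causal 3-pole Butterworth filters applied to the derivative.
#' @param filter_order Butterworth order (poles).
#' @param peak_threshold Candidate threshold on the filtered derivative
#'   trace; `NULL` picks 5 robust (MAD-based) s.d. of the filtered trace.
#' @param window Candidate window length in samples (odd).
#' @param shape_cutoff Maximum DTW distance to the template; `NULL` sets it
#'   automatically (see [detect_spikes()]).
#' @param amp_cutoff Minimum raw-trace spike amplitude; `NULL` = automatic.
#' @param refractory_ms Minimum separation between candidate peaks.
#' @param onset_smooth Samples over which the second derivative is smoothed
#'   when locating spike onsets.
#' @param invert Operate on the negated trace (EMG events of inverted
#'   polarity).
#' @return A list of class `spike_params`.
#' @export
spike_params <- function(fs = 50000, hp_cutoff = 209, lp_cutoff = 898,
                         filter_order = 3, peak_threshold = NULL,
                         window = 251, shape_cutoff = NULL,
                         amp_cutoff = NULL, refractory_ms = 1,
                         onset_smooth = 5, invert = FALSE) {
  if (hp_cutoff >= lp_cutoff) abort("`hp_cutoff` must be below `lp_cutoff`.")
  if (lp_cutoff >= fs / 2) abort("cutoffs must be below the Nyquist frequency.")
  if (window %% 2 == 0) abort("`window` must be odd.")
  structure(
    list(fs = fs, hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
         filter_order = filter_order, peak_threshold = peak_threshold,
         window = as.integer(window), shape_cutoff = shape_cutoff,
         amp_cutoff = amp_cutoff, refractory_ms = refractory_ms,
         onset_smooth = as.integer(onset_smooth), invert = invert),
    class = "spike_params"
  )
}

#' Filtered-derivative preprocessing of a voltage/EMG trace
#'
#' Takes the first difference of the trace (scaled by the sampling rate,
#' so units are trace units per second), then applies a causal 3-pole
#' Butterworth high-pass at 209 Hz followed by a causal 3-pole low-pass
#' at 898 Hz. The rapid reversal of membrane potential at the top of a
#' spike yields a large positive peak in this band-passed derivative.
#' Filters are causal (not zero-phase) so latency structure is preserved
#' for conduction-delay measurements.
#'
#' @param trace Numeric voltage/EMG trace.
#' @param params A [spike_params()].
#' @return Filtered derivative trace, same length as the input.
#' @export
preprocess_trace <- function(trace, params = spike_params()) {
  x <- as.numeric(trace)
  if (params$invert) x <- -x
  if (length(x) <= 10L * params$window) {
    abort("trace too short: need more than 10 candidate windows.")
  }
  d <- c(0, diff(x)) * params$fs
  nyq <- params$fs / 2
  hp <- signal::butter(params$filter_order, params$hp_cutoff / nyq,
                       type = "high")
  lp <- signal::butter(params$filter_order, params$lp_cutoff / nyq,
                       type = "low")
  f1 <- as.numeric(signal::filter(hp, d))
  as.numeric(signal::filter(lp, f1))
}

#' Dynamic time warping distance between two segments
#'
#' Classic dynamic-programming DTW with squared local cost, full
#' alignment of both endpoints and no band constraint. Used to compare a
#' candidate spike's filtered waveform to the cell's template, tolerating
#' small local time shifts that would inflate a plain Euclidean distance.
#'
#' @param a,b Numeric segments of equal length.
#' @return Nonnegative distance (0 iff the segments are identical).
#' @examples
#' dtw_distance(sin(1:50 / 5), sin(1:50 / 5))      # 0
#' @export
dtw_distance <- function(a, b) {
  if (length(a) != length(b)) abort("segments must have equal length.")
  if (length(a) == 0L) abort("segments must be non-empty.")
  .dtw_cost(as.numeric(a), as.numeric(b))
}

# windows around peaks (rows), NA-free; peaks too close to the edges are
# dropped and the surviving peak indices returned as an attribute
peak_windows <- function(x, peaks, window) {
  half <- (window - 1L) %/% 2L
  ok <- peaks - half >= 1L & peaks + half <= length(x)
  peaks <- peaks[ok]
  w <- t(vapply(peaks, function(p) x[(p - half):(p + half)],
                numeric(window)))
  attr(w, "peaks") <- peaks
  w
}

#' Estimate a cell's spike template from seed events
#'
#' Averages peak-aligned windows of the filtered trace, then performs one
#' refinement pass: events whose DTW distance to the provisional mean
#' exceeds the 90th percentile are dropped and the rest re-averaged.
#' Templates are computed per cell because spike amplitude varies, though
#' waveform shape is broadly conserved.
#'
#' @param filtered Filtered derivative trace from [preprocess_trace()].
#' @param seed_peaks Indices of at least 3 seed events (filtered-trace
#'   peaks).
#' @param window Window length (odd samples).
#' @return A list of class `fm_template`: `template` (numeric vector),
#'   `window`, `n_used`, `dropped` (seed indices excluded by refinement).
#' @export
estimate_template <- function(filtered, seed_peaks, window = 251) {
  if (length(seed_peaks) < 3L) abort("need at least 3 seed events.")
  w <- peak_windows(filtered, as.integer(seed_peaks), window)
  if (nrow(w) < 3L) abort("need at least 3 seed events inside the trace.")
  peaks <- attr(w, "peaks")
  mean0 <- colMeans(w)
  d <- .dtw_cost_many(w, mean0)
  cut <- quantile(d, 0.9, names = FALSE)
  keep <- d <= cut
  structure(
    list(template = colMeans(w[keep, , drop = FALSE]),
         window = as.integer(window),
         n_used = sum(keep),
         dropped = peaks[!keep]),
    class = "fm_template"
  )
}

#' Detect spikes in a voltage or EMG trace
#'
#' The four-step detector: the trace is band-pass-derivative filtered;
#' candidates are local maxima of the filtered trace above the peak
#' threshold with at least the refractory separation; each candidate is
#' scored by DTW distance to the template and by raw-trace amplitude
#' (peak minus the preceding local baseline); candidates with distance at
#' or below the shape cutoff and amplitude at or above the amplitude
#' cutoff are accepted. Spike onsets are located per accepted spike with
#' [locate_onset()].
#'
#' When shape/amplitude cutoffs are not given they are set by 2-means
#' clustering of candidates in (log distance, amplitude): the accepted
#' component is the high-amplitude/low-distance one, and acceptance
#' requires clear separation between the two components (otherwise no
#' spike population is declared and nothing is accepted). The study set
#' these cutoffs interactively per cell, so explicit values always
#' override.
#'
#' @param trace Raw voltage (mV) or EMG (pA) trace.
#' @param template An `fm_template`, or `NULL` to self-seed from the top
#'   20 candidates by filtered peak height.
#' @param params A [spike_params()] (window must match the template).
#' @return A tibble of class `fm_spikes` with one row per accepted spike:
#'   `peak_index`, `onset_index`, `peak_s`, `onset_s`, `amplitude`,
#'   `shape_distance`. The candidate table (all scored candidates) is
#'   attached as attribute `"candidates"`, the template as `"template"`.
#' @export
detect_spikes <- function(trace, template = NULL, params = spike_params()) {
  x_raw <- as.numeric(trace)
  x <- if (params$invert) -x_raw else x_raw
  filt <- preprocess_trace(trace, params)
  thr <- params$peak_threshold %||%
    (5 * mad(filt, constant = 1.4826))
  min_sep <- max(1L, round(params$refractory_ms / 1000 * params$fs))
  cand <- local_maxima(filt, threshold = thr, min_sep = min_sep)
  empty <- tibble::tibble(
    peak_index = integer(), onset_index = integer(), peak_s = numeric(),
    onset_s = numeric(), amplitude = numeric(), shape_distance = numeric()
  )
  if (length(cand) == 0L) {
    class(empty) <- c("fm_spikes", class(empty))
    return(empty)
  }
  if (is.null(template)) {
    seeds <- cand[order(filt[cand], decreasing = TRUE)]
    seeds <- head(seeds, 20L)
    if (length(seeds) < 3L) {
      class(empty) <- c("fm_spikes", class(empty))
      return(empty)
    }
    template <- estimate_template(filt, seeds, params$window)
  }
  if (!inherits(template, "fm_template")) abort("`template` must be an fm_template.")
  if (template$window != params$window) {
    abort("template window does not match params$window.")
  }
  if (all(template$template == 0)) abort("degenerate all-zero template.")

  w <- peak_windows(filt, cand, params$window)
  cand <- attr(w, "peaks")
  if (length(cand) == 0L) {
    class(empty) <- c("fm_spikes", class(empty))
    return(empty)
  }
  dist <- .dtw_cost_many(w, template$template)
  # raw amplitude: local peak minus preceding baseline (median over the
  # half-window before the event)
  half <- (params$window - 1L) %/% 2L
  amp <- vapply(cand, function(p) {
    pre <- x[max(1L, p - half):max(1L, p - 10L)]
    lo <- max(1L, p - round(params$fs / 1000))
    hi <- min(length(x), p + round(params$fs / 1000))
    max(x[lo:hi]) - median(pre)
  }, numeric(1))

  cuts <- resolve_cutoffs(dist, amp, params)
  keep <- dist <= cuts$shape & amp >= cuts$amp
  peaks <- cand[keep]
  onsets <- vapply(peaks, function(p) {
    locate_onset(x, p, onset_smooth = params$onset_smooth,
                 search = half)
  }, integer(1))
  out <- tibble::tibble(
    peak_index = peaks,
    onset_index = onsets,
    peak_s = (peaks - 1L) / params$fs,
    onset_s = (onsets - 1L) / params$fs,
    amplitude = amp[keep],
    shape_distance = dist[keep]
  )
  class(out) <- c("fm_spikes", class(out))
  attr(out, "candidates") <- tibble::tibble(
    peak_index = cand, amplitude = amp, shape_distance = dist,
    accepted = keep
  )
  attr(out, "template") <- template
  attr(out, "cutoffs") <- cuts
  out
}

# automatic shape/amplitude cutoffs by 2-means on (log distance, amplitude);
# explicit parameter values override. Acceptance requires the two components
# to be well separated in amplitude, else no spike population is declared.
resolve_cutoffs <- function(dist, amp, params) {
  shape <- params$shape_cutoff
  ampcut <- params$amp_cutoff
  if (!is.null(shape) && !is.null(ampcut)) {
    return(list(shape = shape, amp = ampcut, auto = FALSE))
  }
  if (length(dist) < 4L) {
    return(list(shape = shape %||% Inf, amp = ampcut %||% Inf, auto = TRUE))
  }
  feats <- scale(cbind(log(dist + 1e-12), amp))
  km <- kmeans(feats, centers = 2L, nstart = 5L)
  m_amp <- tapply(amp, km$cluster, mean)
  s_amp <- tapply(amp, km$cluster, sd)
  hi <- which.max(m_amp)
  lo <- which.min(m_amp)
  sep <- (m_amp[hi] - m_amp[lo]) /
    (sum(s_amp, na.rm = TRUE) + 1e-12)
  if (hi == lo || !is.finite(sep) || sep < 2) {
    # no separable spike component
    return(list(shape = shape %||% -Inf, amp = ampcut %||% Inf, auto = TRUE))
  }
  in_hi <- km$cluster == hi
  list(
    shape = shape %||% max(dist[in_hi]),
    amp = ampcut %||% ((min(amp[in_hi]) + max(amp[!in_hi])) / 2),
    auto = TRUE
  )
}

#' Locate a spike's onset from the raw trace
#'
#' The onset is taken as the point of maximal acceleration of the
#' membrane potential: the second difference of the raw trace, smoothed
#' over `onset_smooth` samples, is maximised over the half window
#' preceding the peak. Always returns an index in that window.
#'
#' @param trace Raw trace.
#' @param peak_index Index of the spike peak.
#' @param onset_smooth Moving-average width (samples) for the second
#'   difference.
#' @param search Number of samples before the peak to search.
#' @return Integer onset index (`<= peak_index`).
#' @export
locate_onset <- function(trace, peak_index, onset_smooth = 5, search = 125) {
  x <- as.numeric(trace)
  p <- as.integer(peak_index)
  if (p <= max(3L, search %/% 8L) || p > length(x)) {
    abort("peak too close to the trace boundary.")
  }
  lo <- max(2L, p - search)
  seg <- x[(lo - 1L):min(length(x), p + 1L)]
  acc <- diff(diff(seg))
  if (onset_smooth > 1L) {
    acc <- as.numeric(stats::filter(acc, rep(1 / onset_smooth, onset_smooth),
                                    sides = 2L))
  }
  idx <- seq_along(acc)
  valid <- !is.na(acc) & (lo + idx - 1L) <= p
  if (!any(valid)) return(p)
  as.integer(lo + idx[valid][which.max(acc[valid])] - 1L)
}
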