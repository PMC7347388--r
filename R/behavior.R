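#' Percent change in walking speed around a stimulus
#'
#' Averages walking speed over the stimulation period plus the following
#' 200 ms, subtracts the speed at stimulus onset and divides by the onset
#' speed, in percent. Trials with (near-)zero onset speed are undefined
#' and return `NA`.
#'
#' @param speed Forward-speed trace (mm/s).
#' @param onset_idx Sample index of stimulus onset.
#' @param stim_ms Stimulus duration (ms).
#' @param fs Sampling rate of the trace (Hz).
#' @param post_ms Extra averaging window after the stimulus (ms).
#' @param eps Onset speeds at or below this are treated as undefined.
#' @return Percent change (scalar; `NA` if undefined).
#' @export
percent_speed_change <- function(speed, onset_idx, stim_ms, fs = 30,
                                 post_ms = 200, eps = 1e-6) {
  v0 <- speed[onset_idx]
  if (is.na(v0) || v0 <= eps) return(NA_real_)
  last <- min(length(speed), onset_idx + round((stim_ms + post_ms) / 1000 * fs))
  if (last <= onset_idx) abort("trace ends at stimulus onset.")
  100 * (mean(speed[(onset_idx + 1L):last]) - v0) / v0
}

#' Did a stationary fly initiate walking after the stimulus?
#'
#' A walk initiation is sustained walking above the speed threshold
#' (default 3 mm/s) within the half second following stimulus onset;
#' "sustained" means above threshold for at least `sustained_frac` of the
#' window (default 50%).
#'
#' @param speed Forward-speed trace (mm/s).
#' @param onset_idx Stimulus-onset sample index.
#' @param fs Sampling rate (Hz).
#' @param threshold Walking speed threshold (mm/s).
#' @param window_ms Post-onset window (ms).
#' @param sustained_frac Fraction of the window that must exceed the
#'   threshold.
#' @return Logical.
#' @export
walk_initiation <- function(speed, onset_idx, fs = 30, threshold = 3,
                            window_ms = 500, sustained_frac = 0.5) {
  need <- onset_idx + ceiling(window_ms / 1000 * fs)
  if (length(speed) < need) abort("trace does not cover onset + 500 ms.")
  win <- speed[(onset_idx + 1L):need]
  mean(win > threshold) >= sustained_frac
}

#' Two-sample bootstrap test
#'
#' The study's resampling test: both groups are pooled, group-sized
#' samples are drawn with replacement (i.e. in proportion to the number
#' of trials per group), and the difference in the statistic between the
#' resampled groups forms the null distribution. The two-tailed p-value
#' is the fraction of draws at least as extreme (in absolute value) as
#' the observed difference, with add-one smoothing so p is never exactly
#' zero.
#'
#' @param outcomes_a,outcomes_b Numeric or logical outcome vectors.
#' @param statistic `"fraction"` (binary outcomes) or `"mean"`.
#' @param n_draws Number of bootstrap draws (10,000 in the study).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `statistic`, `observed_a`, `observed_b`,
#'   `difference`, `p_value`, `n_draws`.
#' @export
bootstrap_two_sample <- function(outcomes_a, outcomes_b,
                                 statistic = c("fraction", "mean"),
                                 n_draws = 10000, seed = NULL) {
  statistic <- match.arg(statistic)
  a <- as.numeric(outcomes_a)
  b <- as.numeric(outcomes_b)
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be non-empty.")
  if (statistic == "fraction" && !all(c(a, b) %in% c(0, 1))) {
    abort("`fraction` requires binary outcomes.")
  }
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  nb <- length(b)
  p <- with_seed(seed, {
    draws_a <- matrix(sample(pool, na * n_draws, replace = TRUE), nrow = na)
    draws_b <- matrix(sample(pool, nb * n_draws, replace = TRUE), nrow = nb)
    null_diff <- colMeans(draws_a) - colMeans(draws_b)
    (sum(abs(null_diff) >= abs(obs)) + 1) / (n_draws + 1)
  })
  tibble::tibble(
    statistic = statistic,
    observed_a = mean(a), observed_b = mean(b),
    difference = obs, p_value = p, n_draws = n_draws
  )
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard step-up procedure at level `q`: with ordered p-values
#' p(1) <= ... <= p(m), reject all hypotheses up to the largest i with
#' p(i) <= i q / m. Adjusted values are the usual BH-adjusted p-values
#' (monotone cumulative minima), computed with `stats::p.adjust`.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return A tibble in the input order: `p_value`, `p_adjusted`,
#'   `rejected`. Empty input gives an empty tibble.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5))  # three rejections at q = 0.05
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) {
    return(tibble::tibble(p_value = numeric(), p_adjusted = numeric(),
                          rejected = logical()))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must be in [0, 1].")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, p_adjusted = adj, rejected = adj <= q)
}

#' Compare walk initiation or speed change between two groups
#'
#' Convenience wrapper tying a trial table to the bootstrap test: for
#' `endpoint = "initiation"` it compares the fraction of stationary
#' trials that initiated walking; for `endpoint = "speed_change"` it
#' compares mean percent speed change of walking trials.
#'
#' @param trials A trial table such as from [simulate_behavior_trials()].
#' @param endpoint `"initiation"` or `"speed_change"`.
#' @param groups Length-2 character vector naming the groups to compare.
#' @param stim_ms Stimulus duration used for the speed-change window
#'   (defaults to each trial's `stim_ms`).
#' @param fs Speed trace sampling rate (Hz).
#' @param n_draws,seed Passed to [bootstrap_two_sample()].
#' @return The one-row tibble from [bootstrap_two_sample()].
#' @export
compare_groups <- function(trials, endpoint = c("initiation", "speed_change"),
                           groups = c("control", "treated"), stim_ms = NULL,
                           fs = 30, n_draws = 10000, seed = NULL) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "initiation") {
    get <- function(g) {
      tr <- trials[trials$group == g & trials$category == "Stationary", ]
      as.numeric(tr$outcome)
    }
    bootstrap_two_sample(get(groups[1L]), get(groups[2L]),
                         statistic = "fraction", n_draws = n_draws,
                         seed = seed)
  } else {
    get <- function(g) {
      tr <- trials[trials$group == g & trials$category == "Walking", ]
      vapply(seq_len(nrow(tr)), function(i) {
        percent_speed_change(tr$speed[[i]], tr$onset_idx[i],
                             stim_ms %||% tr$stim_ms[i], fs = fs)
      }, numeric(1))
    }
    a <- get(groups[1L]); b <- get(groups[2L])
    bootstrap_two_sample(a[!is.na(a)], b[!is.na(b)], statistic = "mean",
                         n_draws = n_draws, seed = seed)
  }
}
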