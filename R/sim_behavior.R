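#' Simulate an optogenetic behavioral trial table
#'
#' Emulates the tethered-walking experiments: for each group (control vs
#' treated), `n_per_group` stationary trials with Bernoulli walk-initiation
#' outcomes, and `n_per_group` walking trials with 30 Hz forward-speed
#' traces that undergo a stimulus-locked multiplicative speed change of
#' `speed_effect` during the stimulus plus the following 200 ms.
#'
#' @param p_control,p_treated Walk-initiation probabilities per group.
#' @param n_per_group Trials per group and category.
#' @param speed_effect Multiplicative speed change in the treated group's
#'   walking trials (1 = no change). Controls always have effect 1.
#' @param stim_ms Stimulus duration (ms).
#' @param baseline_speed Mean pre-stimulus speed (mm/s).
#' @param fps Speed trace sampling rate (Hz).
#' @param trial_dur_s Trial length (s); stimulus onset at 2 s.
#' @param noise_sd Speed noise s.d. (mm/s), smoothed to walking-like
#'   fluctuations.
#' @param seed Integer seed.
#' @return A tibble (class `fm_trials`) with columns `trial_id`, `group`,
#'   `stim_ms`, `category` ("Stationary"/"Walking"), `outcome` (logical,
#'   stationary trials only), `onset_idx`, and list-column `speed`
#'   (walking trials only).
#' @export
simulate_behavior_trials <- function(p_control, p_treated, n_per_group = 30,
                                     speed_effect = 1, stim_ms = 90,
                                     baseline_speed = 8, fps = 30,
                                     trial_dur_s = 4, noise_sd = 1,
                                     seed = 1L) {
  if (any(c(p_control, p_treated) < 0) || any(c(p_control, p_treated) > 1)) {
    abort("probabilities must be in [0, 1].")
  }
  with_seed(seed, {
    n <- floor(trial_dur_s * fps)
    onset <- floor(2 * fps) + 1L
    win <- (onset + 1L):min(n, onset + round((stim_ms + 200) / 1000 * fps))
    smooth_speed <- function() {
      raw <- rnorm(n + 10L, sd = noise_sd)
      sm <- as.numeric(stats::filter(raw, rep(1 / 5, 5), sides = 2L))
      pmax(0, baseline_speed + sm[6:(n + 5L)])
    }
    mk_group <- function(group, p_init, effect) {
      stat <- tibble::tibble(
        trial_id = NA_integer_, group = group, stim_ms = stim_ms,
        category = "Stationary",
        outcome = runif(n_per_group) < p_init,
        onset_idx = onset, speed = vector("list", n_per_group)
      )
      walk <- purrr::map_dfr(seq_len(n_per_group), function(i) {
        sp <- smooth_speed()
        sp[win] <- sp[win] * effect
        tibble::tibble(trial_id = NA_integer_, group = group,
                       stim_ms = stim_ms, category = "Walking",
                       outcome = NA, onset_idx = onset, speed = list(sp))
      })
      dplyr::bind_rows(stat, walk)
    }
    out <- dplyr::bind_rows(
      mk_group("control", p_control, 1),
      mk_group("treated", p_treated, speed_effect)
    )
    out$trial_id <- seq_len(nrow(out))
    class(out) <- c("fm_trials", class(out))
    out
  })
}
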